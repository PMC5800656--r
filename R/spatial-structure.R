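#' Lattice of target and non-target cells
#'
#' A `spatial_structure` is a rectangular lattice with periodic boundary
#' conditions in which every site permanently carries either a target cell
#' (susceptible to the virus) or a non-target cell. Neighborhood is the four
#' orthogonal (von Neumann) neighbors, so the inverse neighborhood size is
#' theta = 1/4. The target/non-target mask never changes during epidemic or
#' evolutionary dynamics; it only sets the arena.
#'
#' @param mask logical (or 0/1) matrix; `TRUE` marks a target cell. Rows are
#'   lattice rows; indexing is row-major and 0-based in the compiled code.
#' @return an object of class `spatial_structure` with elements `mask`
#'   (logical matrix), `height` (rows) and `width` (columns).
#' @seealso [measure_moments()], [generate_csr()], [generate_structure_mh()],
#'   [generate_deterministic()]
#' @export
spatial_structure <- function(mask) {
  if (!is.matrix(mask) || nrow(mask) < 1L || ncol(mask) < 1L)
    stop("`mask` must be a non-empty matrix")
  if (is.numeric(mask)) {
    if (!all(mask %in% c(0, 1))) stop("numeric `mask` must contain only 0/1")
    mask <- mask == 1
  }
  if (!is.logical(mask) || anyNA(mask))
    stop("`mask` must be logical or 0/1 with no missing values")
  structure(list(mask = mask, height = nrow(mask), width = ncol(mask)),
            class = "spatial_structure")
}

#' @export
print.spatial_structure <- function(x, ...) {
  m <- measure_moments(x)
  cat(sprintf("<spatial_structure %d x %d (periodic, 4-neighbor)>\n",
              x$height, x$width))
  cat(sprintf("  x_C = %.4f, p_CC = %.4f", m$x_C, m$p_CC))
  if (is.na(m$clustering)) cat(", clustering undefined (x_C = 0)\n")
  else cat(sprintf(", clustering p_CC/x_C^2 = %.4f\n", m$clustering))
  invisible(x)
}

#' Uniform (all-target or all-non-target) lattice
#'
#' Degenerate constructor for saturated lattices, which [generate_csr()]
#' deliberately refuses to produce.
#'
#' @param dims integer vector `c(rows, cols)`.
#' @param target logical; fill with target cells (`TRUE`) or non-target.
#' @export
uniform_structure <- function(dims = c(100L, 100L), target = TRUE) {
  spatial_structure(matrix(target, dims[1], dims[2]))
}

#' First and second spatial moments of a target-cell configuration
#'
#' `spatial_moments` records the singlet density x_C (fraction of sites that
#' are target cells) and the pair density p_CC (fraction of ordered
#' (site, neighbor) pairs in which both members are target cells, out of the
#' 4N such pairs on a periodic lattice). From these it derives the
#' conditional neighbor probability q_C/C = p_CC/x_C and the clustering index
#' p_CC/x_C^2, which equals 1 under complete spatial randomness (CSR),
#' exceeds 1 for aggregated configurations and falls below 1 for
#' over-dispersed ones. When x_C = 0 the conditional quantities are
#' undefined and stored as `NA` (flagged when printed).
#'
#' @param x_C singlet density of target cells in \[0, 1\].
#' @param p_CC ordered pair density of target-target neighbor pairs; must
#'   satisfy 0 <= p_CC <= x_C.
#' @return object of class `spatial_moments`: list with `x_C`, `p_CC`,
#'   `q_C_given_C`, `clustering`.
#' @export
spatial_moments <- function(x_C, p_CC) {
  stopifnot(is.numeric(x_C), length(x_C) == 1L, is.numeric(p_CC),
            length(p_CC) == 1L)
  if (x_C < 0 || x_C > 1) stop("x_C must lie in [0, 1]")
  if (p_CC < -1e-12 || p_CC > x_C + 1e-12)
    stop("p_CC must satisfy 0 <= p_CC <= x_C (p_CO = x_C - p_CC >= 0)")
  p_CC <- min(max(p_CC, 0), x_C)
  und <- x_C == 0
  structure(list(
    x_C = x_C,
    p_CC = p_CC,
    q_C_given_C = if (und) NA_real_ else p_CC / x_C,
    clustering = if (und) NA_real_ else p_CC / x_C^2
  ), class = "spatial_moments")
}

#' @export
print.spatial_moments <- function(x, ...) {
  cat(sprintf("<spatial_moments> x_C = %.6g, p_CC = %.6g\n", x$x_C, x$p_CC))
  if (is.na(x$clustering))
    cat("  q_C/C and clustering undefined (x_C = 0)\n")
  else
    cat(sprintf("  q_C/C = %.6g, clustering p_CC/x_C^2 = %.6g\n",
                x$q_C_given_C, x$clustering))
  invisible(x)
}

# Ordered target-target adjacency count with periodic wrap. Each unordered
# edge is counted twice, matching the p_sigma-sigma' = x_sigma q_sigma'/sigma
# bookkeeping in which pairs are ordered.
count_cc_ordered <- function(mask) {
  right <- mask[, c(seq_len(ncol(mask))[-1], 1L), drop = FALSE]
  down  <- mask[c(seq_len(nrow(mask))[-1], 1L), , drop = FALSE]
  2L * (sum(mask & right) + sum(mask & down))
}

#' Measure the spatial moments of a lattice
#'
#' Counts target sites and ordered target-target adjacencies (4 orthogonal
#' neighbors, periodic wrap) and returns them as densities. Counting ordered
#' pairs from either endpoint is identical by construction, so the measured
#' p_CC is symmetric.
#'
#' @param structure a [spatial_structure()].
#' @return a [spatial_moments()] object.
#' @export
measure_moments <- function(structure) {
  stopifnot(inherits(structure, "spatial_structure"))
  n <- structure$height * structure$width
  if (n == 0L) stop("zero-size lattice")
  x_C <- sum(structure$mask) / n
  p_CC <- count_cc_ordered(structure$mask) / (4 * n)
  spatial_moments(x_C, p_CC)
}

#' Completely spatially random (CSR) lattice
#'
#' Each site is independently a target cell with probability `x_C`, so the
#' expected measured pair density is x_C^2 (clustering index 1). Saturated
#' requests (`x_C` 0 or 1) are rejected; use [uniform_structure()] for those
#' degenerate cases.
#'
#' @param x_C target-cell probability, strictly inside (0, 1).
#' @param dims `c(rows, cols)`, default 100 x 100.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @export
generate_csr <- function(x_C, dims = c(100L, 100L), seed = NULL) {
  if (!is.numeric(x_C) || length(x_C) != 1L || x_C <= 0 || x_C >= 1)
    stop("x_C must lie strictly inside (0, 1); use uniform_structure() for saturated lattices")
  with_seed(seed, {
    mask <- matrix(runif(dims[1] * dims[2]) < x_C, dims[1], dims[2])
    spatial_structure(mask)
  })
}

#' Lattice with prescribed pair density via Metropolis swaps
#'
#' Generates a lattice whose singlet density is exactly `round(x_C * N) / N`
#' (the target-cell count is fixed up front and conserved by swaps) and whose
#' measured pair density p_CC is driven to `p_CC_target` by repeatedly
#' proposing to exchange a uniformly chosen target site with a uniformly
#' chosen non-target site, accepting a swap only if it strictly reduces
#' |p_CC - target| (ties rejected; `mh_rule = "strict"` is the only rule
#' implemented).
#'
#' @param x_C desired singlet density (made exact up to lattice resolution).
#' @param p_CC_target desired ordered pair density; must be feasible,
#'   i.e. max(0, 2 x_C - 1) <= p_CC_target <= x_C.
#' @param dims `c(rows, cols)`.
#' @param seed optional integer seed.
#' @param tol convergence tolerance on |measured p_CC - target|
#'   (default 1e-3).
#' @param max_iter maximum number of swap proposals (default 1e6).
#' @param mh_rule acceptance rule; only `"strict"` (accept-if-improves) is
#'   available.
#' @return a [spatial_structure()] with attributes `achieved` (the measured
#'   [spatial_moments()]) and `iterations` (proposals examined).
#'   If the tolerance is not reached within `max_iter`, an error of class
#'   `pairsis_mh_error` is signalled carrying the best-achieved p_CC in its
#'   `best_p_CC` field.
#' @export
generate_structure_mh <- function(x_C, p_CC_target, dims = c(100L, 100L),
                                  seed = NULL, tol = 1e-3, max_iter = 1e6,
                                  mh_rule = "strict") {
  mh_rule <- match.arg(mh_rule, "strict")
  if (x_C <= 0 || x_C >= 1) stop("x_C must lie strictly inside (0, 1)")
  lo <- max(0, 2 * x_C - 1)
  if (p_CC_target < lo - 1e-12 || p_CC_target > x_C + 1e-12)
    stop(sprintf("infeasible p_CC_target %.4g: must lie in [%.4g, %.4g] for x_C = %.4g",
                 p_CC_target, lo, x_C, x_C))
  n <- as.integer(dims[1]) * as.integer(dims[2])
  k <- round(x_C * n)
  if (k == 0L || k == n) stop("x_C rounds to a saturated lattice at these dims")
  with_seed(seed, {
    mask <- matrix(FALSE, dims[1], dims[2])
    mask[sample.int(n, k)] <- TRUE
    res <- mh_refine_cpp(mask, p_CC_target, tol, as.double(max_iter))
    st <- spatial_structure(res$mask)
    ach <- measure_moments(st)
    if (abs(ach$p_CC - p_CC_target) > tol * (1 + 1e-9)) {
      cond <- structure(
        class = c("pairsis_mh_error", "error", "condition"),
        list(message = sprintf(
          "Metropolis refinement did not reach p_CC = %.4g within %g proposals (best achieved %.6g)",
          p_CC_target, max_iter, ach$p_CC),
          call = sys.call(-1), best_p_CC = ach$p_CC,
          iterations = res$iterations))
      stop(cond)
    }
    attr(st, "achieved") <- ach
    attr(st, "iterations") <- res$iterations
    st
  })
}

#' Deterministic target-cell patterns
#'
#' Named reference configurations: width-`period` vertical stripes,
#' `period` x `period` checkerboard blocks, and a Sierpinski-gasket raster
#' (sites (r, c), 0-based, with `bitwAnd(r, c) == 0`). Stripes and
#' checkerboards require `dims` divisible by the pattern period; their exact
#' moments are x_C = 1/2 with p_CC = 1/4 for width-1 stripes and p_CC = 2/5
#' for 5 x 5 checkerboard blocks on a 100 x 100 torus. The gasket's moments
#' depend on the rasterization and are reported as measured, not asserted.
#'
#' @param pattern one of `"stripes"`, `"checkerboard"`, `"sierpinski"`.
#' @param period stripe width or checkerboard block size (ignored for the
#'   gasket).
#' @param dims `c(rows, cols)`.
#' @export
generate_deterministic <- function(pattern = c("stripes", "checkerboard", "sierpinski"),
                                   period = 1L, dims = c(100L, 100L)) {
  pattern <- match.arg(pattern)
  nr <- as.integer(dims[1]); nc <- as.integer(dims[2])
  period <- as.integer(period)
  if (pattern %in% c("stripes", "checkerboard")) {
    if (period < 1L) stop("period must be a positive integer")
    if (pattern == "stripes" && nc %% (2L * period) != 0L)
      stop("stripes: number of columns must be divisible by 2 * period")
    if (pattern == "checkerboard" &&
        (nr %% (2L * period) != 0L || nc %% (2L * period) != 0L))
      stop("checkerboard: both dims must be divisible by 2 * period")
  }
  mask <- switch(pattern,
    stripes = {
      col_on <- ((seq_len(nc) - 1L) %/% period) %% 2L == 0L
      matrix(rep(col_on, each = nr), nr, nc)
    },
    checkerboard = {
      rb <- ((seq_len(nr) - 1L) %/% period) %% 2L
      cb <- ((seq_len(nc) - 1L) %/% period) %% 2L
      outer(rb, cb, function(a, b) (a + b) %% 2L == 0L)
    },
    sierpinski = {
      r <- seq_len(nr) - 1L
      c <- seq_len(nc) - 1L
      outer(r, c, function(a, b) bitwAnd(a, b) == 0L)
    })
  spatial_structure(mask)
}

#' Read / write a lattice as a plain-text 0/1 matrix
#'
#' One lattice row per line, characters `0` (non-target) and `1` (target),
#' optional whitespace between characters. Write-then-read is the identity on
#' the mask.
#'
#' @param path file path.
#' @rdname structure_io
#' @export
read_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty structure file")
  rows <- lapply(lines, function(ln) {
    ch <- strsplit(gsub("[[:space:]]", "", ln), "")[[1]]
    if (length(ch) == 0L || !all(ch %in% c("0", "1")))
      stop("structure file must contain only 0/1 characters and whitespace")
    ch == "1"
  })
  len <- lengths(rows)
  if (length(unique(len)) != 1L) stop("ragged rows in structure file")
  spatial_structure(do.call(rbind, rows))
}

#' @param structure a [spatial_structure()] to serialize.
#' @rdname structure_io
#' @export
write_structure <- function(structure, path) {
  stopifnot(inherits(structure, "spatial_structure"))
  lines <- apply(structure$mask, 1L, function(r) paste(as.integer(r), collapse = ""))
  writeLines(lines, path)
  invisible(path)
}
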