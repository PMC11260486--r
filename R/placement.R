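#' Gaussian kernel density of feature positions
#'
#' Exact (non-binned) Gaussian kernel density estimate with the
#' Scott-rule bandwidth scaled by a smoothing factor:
#' `h = bw_adjust * n^(-1/5) * sd(x)`. The default `bw_adjust = 0.5`
#' follows the plotting convention used for positional densities of
#' genes and BGCs on linear chromosomes. Every observation contributes
#' equal kernel mass, so long and short features weigh identically once
#' reduced to midpoints. The grid spans `[min - 3h, max + 3h]`.
#'
#' @param x Observations (bp offsets or `arm_pos` values); at least two,
#'   finite, with non-zero variance.
#' @param bw_adjust Bandwidth scaling factor.
#' @param grid_n Number of grid points.
#' @param bw Bandwidth override (same units as `x`); when given,
#'   `bw_adjust` is ignored.
#' @return A `density_curve`: list with `grid`, `density`, `bw`, `n_obs`.
#' @export
kde_density <- function(x, bw_adjust = 0.5, grid_n = 512, bw = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) stop("need at least 2 observations for a density")
  if (any(!is.finite(x))) stop("observations must be finite")
  sdx <- sd(x)
  if (sdx == 0)
    stop("zero variance in observations; consider a rug plot instead")
  h <- if (is.null(bw)) bw_adjust * n^(-1 / 5) * sdx else bw
  grid <- seq(min(x) - 3 * h, max(x) + 3 * h, length.out = grid_n)
  dens <- numeric(grid_n)
  for (chunk in split(x, ceiling(seq_along(x) / 2000))) {
    dens <- dens + rowSums(dnorm(outer(grid, chunk, "-"), sd = h))
  }
  structure(list(grid = grid, density = dens / n, bw = h, n_obs = n),
            class = "density_curve")
}

#' @export
print.density_curve <- function(x, ...) {
  cat(sprintf("<density_curve> n_obs=%d bw=%.4g grid=[%.4g, %.4g] x %d\n",
              x$n_obs, x$bw, min(x$grid), max(x$grid), length(x$grid)))
  invisible(x)
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

#' Integrated density mass over an interval
#'
#' Trapezoidal integral of a [kde_density()] curve over
#' `[lower, upper]`, with linear interpolation at the interval ends.
#'
#' @param curve A `density_curve`.
#' @param lower,upper Integration bounds.
#' @return The integrated mass (about 1 over the whole grid).
#' @export
density_mass <- function(curve, lower = -Inf, upper = Inf) {
  g <- curve$grid
  d <- curve$density
  lower <- max(lower, g[1])
  upper <- min(upper, g[length(g)])
  if (lower >= upper) return(0)
  f <- stats::approxfun(g, d)
  inside <- g > lower & g < upper
  xs <- c(lower, g[inside], upper)
  trapz(xs, f(xs))
}

#' Per-category positional densities of protoclusters
#'
#' One density curve per protocluster category, computed on the
#' arm-normalised position `arm_pos` so chromosomes of different lengths
#' pool on a common axis. Curve heights are not comparable between
#' categories (each curve integrates to one on its own observations);
#' the x-axis is. Categories with fewer than two observations get no
#' curve but are still counted.
#'
#' @param centered Centred feature `data.frame` (see [center_offset()])
#'   of protocluster records.
#' @param bw_adjust,grid_n Passed to [kde_density()].
#' @return List with `curves` (named list of `density_curve`) and
#'   `counts` (named integer vector per category).
#' @export
category_density_table <- function(centered, bw_adjust = 0.5,
                                   grid_n = 512) {
  pc <- centered[centered$feature_type == "protocluster", , drop = FALSE]
  if (nrow(pc) == 0L) stop("no protocluster features supplied")
  counts <- table(factor(pc$category, levels = PROTOCLUSTER_CATEGORIES))
  counts <- counts[counts > 0]
  curves <- list()
  for (cat in names(counts)) {
    v <- pc$arm_pos[pc$category == cat]
    if (length(v) >= 2L && sd(v) > 0)
      curves[[cat]] <- kde_density(v, bw_adjust = bw_adjust,
                                   grid_n = grid_n)
  }
  list(curves = curves, counts = as.integer(counts) |>
         setNames(names(counts)))
}

#' Arm asymmetry of feature placement
#'
#' Fraction of features downstream of the chromosome centre (offset > 0
#' in the dnaA-forward frame). Features exactly at the centre are
#' excluded from the fraction and counted separately.
#'
#' @param offsets Signed centre offsets (bp or arm_pos), or a centred
#'   feature `data.frame` with an `offset` column.
#' @return List with `downstream_fraction`, `n`, `n_zero`.
#' @export
arm_asymmetry <- function(offsets) {
  if (is.data.frame(offsets)) offsets <- offsets$offset
  if (length(offsets) == 0L) stop("no offsets supplied")
  n_zero <- sum(offsets == 0)
  nz <- offsets[offsets != 0]
  if (length(nz) == 0L) stop("all offsets are exactly zero")
  list(downstream_fraction = mean(nz > 0), n = length(nz),
       n_zero = n_zero)
}

#' Per-group regression of BGC count on genome length
#'
#' Ordinary least squares of the protocluster/region count on genome
#' length, fitted independently per group (typically per genus), with
#' the Pearson correlation. Groups with fewer than two genomes or
#' without length variance are skipped with a warning.
#'
#' @param genome_length Genome lengths (bp).
#' @param bgc_count BGC counts, same length.
#' @param group Group labels (single group when omitted).
#' @return `data.frame`: `group`, `n`, `slope`, `intercept`, `r`.
#' @export
bgc_count_regression <- function(genome_length, bgc_count, group = NULL) {
  if (length(genome_length) != length(bgc_count))
    stop("genome_length and bgc_count differ in length")
  if (is.null(group)) group <- rep("all", length(genome_length))
  out <- list()
  for (g in unique(group)) {
    i <- group == g
    x <- genome_length[i]
    y <- bgc_count[i]
    if (sum(i) < 2L || sd(x) == 0) {
      warning("group '", g, "' skipped: fewer than 2 genomes or no ",
              "length variance")
      next
    }
    fit <- lm(y ~ x)
    out[[g]] <- data.frame(group = g, n = sum(i),
                           slope = unname(coef(fit)[2]),
                           intercept = unname(coef(fit)[1]),
                           r = if (sd(y) == 0) NA_real_ else cor(x, y),
                           stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) stop("no group could be fitted")
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
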