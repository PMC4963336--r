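#' Rating vectors
#'
#' A per-lesion three-category classification from one source (a human
#' reader, a simulated reader, or a quantitative method).
#'
#' @param lesion_ids unique lesion identifiers.
#' @param category per-lesion categories in
#'   \code{\link{change_categories}}.
#' @param source name of the rater or method.
#' @return A data.frame with columns \code{lesion_id},
#'   \code{category} (factor with the fixed level order), \code{source}.
#' @export
rating_vector <- function(lesion_ids, category, source = "rater") {
  if (anyDuplicated(lesion_ids))
    stop("lesion ids must be unique", call. = FALSE)
  category <- as.character(category)
  if (any(is.na(category)) || !all(category %in% change_categories()))
    stop("categories must all be in {",
         paste(change_categories(), collapse = ", "), "}", call. = FALSE)
  if (length(category) != length(lesion_ids))
    stop("lengths of ids and categories differ", call. = FALSE)
  data.frame(lesion_id = as.character(lesion_ids),
             category = factor(category, levels = change_categories()),
             source = source, stringsAsFactors = FALSE)
}

# Align two rating vectors by lesion id; error on any symmetric difference.
align_ratings <- function(a, b) {
  for (r in list(a, b)) {
    if (!all(c("lesion_id", "category") %in% names(r)))
      stop("rating vectors need 'lesion_id' and 'category' columns",
           call. = FALSE)
  }
  only_a <- setdiff(a$lesion_id, b$lesion_id)
  only_b <- setdiff(b$lesion_id, a$lesion_id)
  if (length(only_a) || length(only_b))
    stop("rating vectors cover different lesions; unmatched ids: ",
         paste(c(only_a, only_b), collapse = ", "), call. = FALSE)
  b <- b[match(a$lesion_id, b$lesion_id), ]
  list(a = factor(as.character(a$category), levels = change_categories()),
       b = factor(as.character(b$category), levels = change_categories()))
}

#' Cross-tabulate two rating vectors
#'
#' @param a,b rating vectors (see \code{\link{rating_vector}}) covering
#'   the same lesion ids.
#' @return A 3x3 integer matrix; rows are \code{a}'s categories, columns
#'   \code{b}'s, in the fixed order (progressive, stable, regressive).
#' @export
contingency <- function(a, b) {
  al <- align_ratings(a, b)
  unclass(table(al$a, al$b))
}

#' Cohen's kappa from a contingency table
#'
#' Chance-corrected agreement \eqn{\kappa = (p_0 - p_e)/(1 - p_e)} with
#' observed agreement \eqn{p_0} = trace/n and chance agreement
#' \eqn{p_e = \sum_i r_i c_i / n^2} from the marginals. A large-sample
#' standard error under independence (Fleiss) provides a two-sided test of
#' \eqn{\kappa = 0}.
#'
#' @param tab square non-negative count matrix (e.g. from
#'   \code{\link{contingency}}).
#' @return An object of class \code{kappa_result}: list with
#'   \code{kappa, p0, pe, n, label} (Landis-Koch strength), \code{se0, z,
#'   p_value}.
#' @export
kappa_from_table <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) != ncol(tab)) stop("table must be square", call. = FALSE)
  if (any(tab < 0)) stop("table counts must be non-negative", call. = FALSE)
  n <- sum(tab)
  if (n < 1) stop("table must contain at least one rating", call. = FALSE)
  p0 <- sum(diag(tab)) / n
  pa <- rowSums(tab) / n
  pb <- colSums(tab) / n
  pe <- sum(pa * pb)
  kappa_result(p0, pe, n, pa, pb)
}

#' Cohen's kappa from marginal counts and an agreement count
#'
#' Unweighted kappa depends only on the two raters' marginal category
#' counts and the number of identically rated items: \eqn{p_0 =
#' n_{agree}/n} and \eqn{p_e} from the marginals alone. This permits exact
#' reconstruction of kappa from published summary tables that list
#' per-method classification tallies and discrepancy counts.
#'
#' @param marginals_a,marginals_b per-category counts for each source, in
#'   the fixed category order; both must sum to \code{n}.
#' @param n_agree number of identically rated items (0..n).
#' @param n total items; defaults to \code{sum(marginals_a)}.
#' @return A \code{kappa_result}, identical to
#'   \code{\link{kappa_from_table}} applied to any table with these
#'   marginals and diagonal sum.
#' @examples
#' # two raters, perfect agreement
#' kappa_from_marginals(c(10, 5, 5), c(10, 5, 5), n_agree = 20)
#' @export
kappa_from_marginals <- function(marginals_a, marginals_b, n_agree,
                                 n = sum(marginals_a)) {
  marginals_a <- as.numeric(marginals_a)
  marginals_b <- as.numeric(marginals_b)
  if (length(marginals_a) != length(marginals_b))
    stop("marginal vectors must have equal length", call. = FALSE)
  if (any(marginals_a < 0) || any(marginals_b < 0))
    stop("marginal counts must be non-negative", call. = FALSE)
  if (abs(sum(marginals_a) - n) > 1e-9 || abs(sum(marginals_b) - n) > 1e-9)
    stop("both marginal vectors must sum to n = ", n, call. = FALSE)
  if (n_agree < 0 || n_agree > n)
    stop("n_agree must lie in [0, n]", call. = FALSE)
  p0 <- n_agree / n
  pa <- marginals_a / n
  pb <- marginals_b / n
  pe <- sum(pa * pb)
  kappa_result(p0, pe, n, pa, pb)
}

# Shared kappa assembly: kappa, Landis-Koch label, Fleiss H0 standard
# error, z and two-sided p.
kappa_result <- function(p0, pe, n, pa, pb) {
  if (pe >= 1 - 1e-12)
    stop("degenerate marginals; kappa undefined", call. = FALSE)
  k <- (p0 - pe) / (1 - pe)
  se0 <- sqrt(pe + pe^2 - sum(pa * pb * (pa + pb))) / ((1 - pe) * sqrt(n))
  z <- if (se0 > 0) k / se0 else NA_real_
  p_value <- if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z))
  structure(list(kappa = k, p0 = p0, pe = pe, n = n,
                 label = interpret_kappa(k), se0 = se0, z = z,
                 p_value = p_value),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f (%s); p0 = %.3f, pe = %.3f, n = %d\n",
              x$kappa, x$label, x$p0, x$pe, as.integer(x$n)))
  if (!is.na(x$p_value))
    cat(sprintf("  H0 kappa = 0: z = %.2f, two-sided p = %.3g\n", x$z, x$p_value))
  invisible(x)
}

#' Landis-Koch interpretation of kappa
#'
#' Conventional verbal strata: below 0 poor; 0 to 0.20 slight; above 0.20
#' to 0.40 fair; above 0.40 to 0.60 moderate; above 0.60 to 0.80
#' substantial; above 0.80 to 1 almost perfect. Applied to the unrounded
#' kappa; upper bounds inclusive.
#'
#' @param k kappa value(s), each <= 1.
#' @return Character vector of strength labels.
#' @export
interpret_kappa <- function(k) {
  if (any(k > 1 + 1e-12)) stop("kappa cannot exceed 1", call. = FALSE)
  vapply(k, function(ki) {
    if (ki < 0) "poor"
    else if (ki <= 0.20) "slight"
    else if (ki <= 0.40) "fair"
    else if (ki <= 0.60) "moderate"
    else if (ki <= 0.80) "substantial"
    else "almost perfect"
  }, character(1))
}

#' Count discrepant ratings between two sources
#'
#' @inheritParams contingency
#' @return List with \code{n_discrepant}, \code{fraction}, and \code{n}.
#' @export
discrepancy_count <- function(a, b) {
  al <- align_ratings(a, b)
  n <- length(al$a)
  nd <- sum(al$a != al$b)
  list(n_discrepant = nd, fraction = nd / n, n = n)
}

#' Format a fraction as a printed percentage
#'
#' Reproduces the convention of the published result tables, which
#' truncate (round toward zero) at the printed precision: 11/52 = 21.15\%
#' prints as \code{"21.1 \%"}, 22/52 = 42.31\% as \code{"42.3 \%"}.
#'
#' @param fraction fraction(s) in [0, 1].
#' @param digits decimal places to keep.
#' @return Numeric percentage(s) truncated to \code{digits} decimals.
#' @export
format_percent <- function(fraction, digits = 1) {
  trunc(100 * fraction * 10^digits) / 10^digits
}

#' Mann-Whitney U test
#'
#' Rank-sum U statistic for the first sample using midranks for ties. The
#' two-sided p-value comes from exact enumeration of all group assignments
#' when \code{min(nx, ny) <= 8} and the pooled sample is small enough to
#' enumerate (total n <= 30), and otherwise from the normal approximation
#' with the usual tie correction of the variance (no continuity
#' correction).
#'
#' @param x,y numeric samples (non-empty).
#' @param exact force (\code{TRUE}) or suppress (\code{FALSE}) exact
#'   enumeration; default \code{NULL} chooses automatically.
#' @return List with \code{U} (for \code{x}), \code{p_value}, and
#'   \code{method}.
#' @export
mann_whitney_u <- function(x, y, exact = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("samples must be non-empty", call. = FALSE)
  if (any(!is.finite(c(x, y)))) stop("samples must be finite", call. = FALSE)
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (is.null(exact)) exact <- min(nx, ny) <= 8 && n <= 30
  if (exact) {
    # enumerate assignments of the smaller group over the pooled midranks
    small_x <- nx <= ny
    m <- min(nx, ny)
    combos <- utils::combn(n, m)
    offs <- m * (m + 1) / 2
    u_small <- colSums(matrix(r[combos], nrow = m)) - offs
    u_dist <- if (small_x) u_small else nx * ny - u_small
    p <- min(1, 2 * min(mean(u_dist <= u + 1e-9), mean(u_dist >= u - 1e-9)))
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - nx * ny / 2) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal approximation with tie correction"
  }
  list(U = u, p_value = p, method = method)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks with a two-sided p-value from the
#' t-approximation (delegated to \code{stats::cor.test}).
#'
#' @param x,y equal-length numeric samples, length >= 3, neither constant.
#' @return List with \code{rho} and \code{p_value}.
#' @export
spearman_rho <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("samples must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rank correlation undefined for constant input", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}
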