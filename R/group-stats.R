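# Scalar statistics layer: mixed-design repeated-measures ANOVA, Spearman
# correlation with Fisher-z confidence intervals, signed-rank post-hocs,
# Bonferroni correction.

#' Mixed-design repeated-measures ANOVA
#'
#' F tests for a design with `session` and `induction` as within-subject
#' factors and `group` as between-subject factor (any subset of these
#' factors may be present). Fitted through a multivariate linear model with
#' type-III sums of squares; sphericity is assessed per within-subject
#' effect (Mauchly) and the Greenhouse-Geisser correction is applied to an
#' effect's degrees of freedom and p-value when its Mauchly p < 0.05.
#' Subjects with incomplete within-subject cells are dropped (cell-wise
#' exclusion) and the analysed n is reported.
#'
#' @param table long-format data.frame with columns `subject`, `value`, and
#'   any of `group` (between), `session`, `induction` (within).
#' @return data.frame with one row per effect: `effect`, `df1`, `df2`, `F`,
#'   `p` (GG-corrected df and p where the correction fired), `gg_epsilon`,
#'   `mauchly_p`, `corrected`, plus attribute `n` (subjects analysed).
#' @export
rm_anova <- function(table) {
  stopifnot(all(c("subject", "value") %in% names(table)))
  within <- intersect(c("session", "induction"), names(table))
  if (length(within) == 0) stop("need at least one within-subject factor", call. = FALSE)
  has_group <- "group" %in% names(table)
  for (f in c(within, if (has_group) "group")) table[[f]] <- factor(table[[f]])

  # wide response matrix: one row per subject, one column per within cell
  # (cell means; lex.order puts the first within factor slowest, matching
  # the idata grid built below)
  cell <- interaction(table[within], drop = FALSE, lex.order = TRUE)
  M <- tapply(table$value, list(factor(table$subject), cell), mean)
  empty <- colSums(!is.na(M)) == 0
  if (any(empty))
    stop("empty within-subject cell(s): ",
         paste(colnames(M)[empty], collapse = ", "), call. = FALSE)
  complete <- stats::complete.cases(M)
  Y <- M[complete, , drop = FALSE]
  subjects <- rownames(Y)
  lv <- lapply(table[within], levels)
  idata <- expand.grid(rev(lv), KEEP.OUT.ATTRS = FALSE)[, rev(seq_along(within)), drop = FALSE]
  names(idata) <- within
  idesign <- stats::as.formula(paste("~", paste(within, collapse = "*")))

  if (has_group) {
    grp <- table$group[match(subjects, table$subject)]
    if (any(tabulate(grp) < 2)) stop("need >= 2 subjects per group", call. = FALSE)
    op <- options(contrasts = c("contr.sum", "contr.poly"))
    on.exit(options(op))
    mod <- stats::lm(Y ~ grp)
  } else {
    mod <- stats::lm(Y ~ 1)
  }
  av <- car::Anova(mod, idata = idata, idesign = idesign, type = 3)
  s <- withCallingHandlers(
    summary(av, multivariate = FALSE),
    warning = function(w) {
      if (grepl("HF eps", conditionMessage(w))) invokeRestart("muffleWarning")
    })
  ut <- s$univariate.tests
  eff_names <- rownames(ut)
  sph <- tryCatch(s$sphericity.tests, error = function(e) NULL)
  ggc <- tryCatch(s$pval.adjustments, error = function(e) NULL)
  if (!is.null(sph) && nrow(sph) == 0) sph <- NULL

  rows <- lapply(eff_names, function(e) {
    if (e == "(Intercept)") return(NULL)
    F_ <- ut[e, "F value"]
    df1 <- ut[e, "num Df"]; df2 <- ut[e, "den Df"]
    p <- ut[e, "Pr(>F)"]
    eps <- NA_real_; mp <- NA_real_; corrected <- FALSE
    if (!is.null(sph) && e %in% rownames(sph)) {
      mp <- sph[e, "p-value"]
      eps <- ggc[e, "GG eps"]
      if (is.finite(mp) && mp < 0.05) {
        corrected <- TRUE
        df1 <- df1 * eps; df2 <- df2 * eps
        p <- ggc[e, "Pr(>F[GG])"]
      }
    }
    name <- sub("^grp", "group", e)
    name <- gsub(":grp", ":group", name)
    data.frame(effect = name, df1 = df1, df2 = df2, F = F_, p = p,
               gg_epsilon = eps, mauchly_p = mp, corrected = corrected)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n") <- nrow(Y)
  out
}

#' Spearman rank correlation with Fisher-z confidence interval
#'
#' Rho by average ranks, two-sided p from the asymptotic t approximation,
#' and a 95% confidence interval from the Fisher z transform of rho with
#' standard error `1 / sqrt(n - 3)`.
#'
#' @param x,y paired numeric vectors (n >= 5 complete pairs; ties allowed).
#' @param conf confidence level (default 0.95).
#' @return data.frame with `rho`, `ci_lower`, `ci_upper`, `p`, `n`.
#' @export
spearman_ci <- function(x, y, conf = 0.95) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 5) stop("need >= 5 paired finite values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant vector", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  rho <- unname(ct$estimate)
  z <- atanh(min(max(rho, -1 + 1e-15), 1 - 1e-15))
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - conf) / 2)
  data.frame(rho = rho, ci_lower = tanh(z - q * se), ci_upper = tanh(z + q * se),
             p = ct$p.value, n = n)
}

#' Bonferroni adjustment
#'
#' `min(1, p * factor)`.
#'
#' @param p raw p-value(s) in `[0, 1]`.
#' @param factor number of comparisons in the family (>= 1).
#' @return Adjusted p-value(s), capped at 1.
#' @export
bonferroni <- function(p, factor) {
  stopifnot(all(p >= 0 & p <= 1), factor >= 1)
  pmin(1, p * factor)
}

#' Bonferroni family size for state temporal parameters
#'
#' Independence counting for a K-state model with `n_params` temporal
#' parameters: one state's activation is determined by the others
#' (`K - 1` independent states) and one parameter is determined by the rest
#' (`n_params - 1` independent parameters), giving
#' `(K - 1) * (n_params - 1)` comparisons -- 21 for 8 states and 4
#' parameters.
#'
#' @param n_states number of HMM states (default 8).
#' @param n_params number of temporal parameters (default 4: MLT, FO, MIL,
#'   NO).
#' @return Integer correction factor.
#' @export
bonferroni_factor <- function(n_states = 8L, n_params = 4L) {
  stopifnot(n_states >= 2, n_params >= 2)
  as.integer((n_states - 1) * (n_params - 1))
}

#' Paired Wilcoxon signed-rank test
#'
#' Signed-rank statistic `W` = sum of ranks of the negative differences
#' `b - a` (so `W = 0` when every `b` exceeds its `a`), with zero
#' differences dropped. Exact p for n <= 25 nonzero differences (no ties),
#' normal approximation with continuity correction otherwise.
#'
#' @param a,b paired numeric vectors.
#' @return data.frame with `W`, `p`, `n` (nonzero differences).
#' @export
wilcoxon_signed_rank <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- b - a
  d <- d[is.finite(d) & d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all differences zero; test undefined")
    return(data.frame(W = NA_real_, p = NA_real_, n = 0L))
  }
  if (n < 5) stop("need >= 5 nonzero differences", call. = FALSE)
  rk <- rank(abs(d))
  W <- sum(rk[d < 0])
  exact <- n <= 25 && !any(duplicated(abs(d)))
  p <- suppressWarnings(
    stats::wilcox.test(b, a, paired = TRUE, exact = exact, correct = TRUE)$p.value)
  data.frame(W = W, p = p, n = n)
}
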