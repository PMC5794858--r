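#' Mixed repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Fits a balanced split-plot design with one between-subjects factor and
#' one or two within-subjects factors via the classical univariate
#' sums-of-squares decomposition (`aov` with subject error strata), and
#' augments every within-subject effect with its Greenhouse-Geisser epsilon
#' (computed from the pooled within-group covariance of the subject-by-cell
#' scores projected onto the effect's orthonormal contrasts), the
#' GG-corrected p value, and partial eta squared. GG-corrected p values are
#' always reported alongside the uncorrected ones, and the output flags
#' which of the two crosses 0.05, so no silent switching occurs.
#'
#' Subjects missing any within-subject cell are excluded listwise with a
#' message; a design that remains unbalanced (unequal replicates of a
#' within cell for a subject) raises an error rather than silently
#' dropping data.
#'
#' @param table Long-format data frame: one row per subject x within-cell,
#'   with columns `subject`, the between factor, the within factor(s) and
#'   `value`.
#' @param within Character vector (length 1 or 2) naming the
#'   within-subjects factor column(s).
#' @param between Name of the between-subjects factor column (or NULL for
#'   a fully within design).
#' @param value Name of the response column (default "value").
#' @param subject Name of the subject id column (default "subject").
#' @return An `erp_anova` object; use [tidy()] for the effect table. The
#'   table columns are effect, df_effect, df_error, ss_effect, ss_error,
#'   F, p, gg_epsilon, p_gg, partial_eta_sq, sig_raw, sig_gg.
#' @export
mixed_anova <- function(table, within, between = NULL, value = "value",
                        subject = "subject") {
  df <- as.data.frame(table)
  stopifnot(all(c(subject, within, value) %in% names(df)))
  if (!is.null(between)) stopifnot(between %in% names(df))
  df$.subj <- factor(df[[subject]])
  for (w in within) df[[w]] <- factor(df[[w]])
  if (!is.null(between)) df[[between]] <- factor(df[[between]])

  # listwise exclusion of subjects with missing cells
  n_cells <- prod(vapply(within, function(w) nlevels(df[[w]]), 1L))
  df <- df[!is.na(df[[value]]), ]
  cell <- interaction(df[, within, drop = FALSE], drop = TRUE)
  if (any(table(df$.subj, cell) > 1)) {
    stop("unbalanced design: replicated within-subject cells", call. = FALSE)
  }
  cnt <- table(df$.subj)
  bad <- names(cnt)[cnt < n_cells]
  if (length(bad)) {
    message(length(bad), " subject(s) excluded listwise (missing cells)")
    df <- df[!(df$.subj %in% bad), ]
    df$.subj <- droplevels(df$.subj)
  }

  wterm <- paste(within, collapse = "*")
  rhs <- if (is.null(between)) wterm else paste(between, "*", wterm)
  fml <- stats::as.formula(paste0(
    "`", value, "` ~ ", rhs, " + Error(.subj/(", wterm, "))"))
  fit <- stats::aov(fml, data = df)
  sm <- summary(fit)

  rows <- list()
  for (stratum in sm) {
    tab <- if (is.list(stratum)) stratum[[1]] else stratum
    rn <- trimws(rownames(tab))
    resid <- rn == "Residuals"
    if (!any(resid)) next
    ss_err <- tab[resid, "Sum Sq"]
    df_err <- tab[resid, "Df"]
    for (i in which(!resid)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        effect = gsub(":", " x ", rn[i]),
        raw_effect = rn[i],
        df_effect = tab[i, "Df"], df_error = df_err,
        ss_effect = tab[i, "Sum Sq"], ss_error = ss_err,
        F = tab[i, "F value"], p = tab[i, "Pr(>F)"]
      )
    }
  }
  res <- dplyr::bind_rows(rows)

  # GG epsilon per within effect (shared by its interaction with `between`)
  res$gg_epsilon <- NA_real_
  for (i in seq_len(nrow(res))) {
    wparts <- intersect(strsplit(res$raw_effect[i], ":")[[1]], within)
    if (length(wparts) == 0) next
    res$gg_epsilon[i] <- gg_epsilon(df, wparts, within, between,
                                    value, ".subj")
  }
  res$p_gg <- ifelse(is.na(res$gg_epsilon), res$p,
                     stats::pf(res$F, res$df_effect * res$gg_epsilon,
                               res$df_error * res$gg_epsilon,
                               lower.tail = FALSE))
  res$partial_eta_sq <- res$ss_effect / (res$ss_effect + res$ss_error)
  res$sig_raw <- res$p < 0.05
  res$sig_gg <- res$p_gg < 0.05
  res$raw_effect <- NULL
  structure(list(table = res, within = within, between = between,
                 n_subjects = nlevels(df$.subj)),
            class = "erp_anova")
}

# Greenhouse-Geisser epsilon for the within effect defined by `wparts`,
# from the pooled (within-group) covariance of subject-by-cell scores
# projected on the effect's orthonormal contrast basis.
gg_epsilon <- function(df, wparts, within, between, value, subject) {
  cell <- do.call(interaction,
                  c(unname(as.list(df[, within, drop = FALSE])),
                    list(drop = FALSE, lex.order = TRUE)))
  wide <- tapply(df[[value]], list(df[[subject]], cell), mean)
  lev <- lapply(within, function(w) levels(df[[w]]))
  names(lev) <- within
  # contrast basis: Kronecker over factors in declaration order (lex.order
  # puts the first within factor slowest); helmert-orthonormal columns for
  # factors in the effect, the uniform mean vector for factors not in it
  basis <- matrix(1, 1, 1)
  for (w in within) {
    k <- length(lev[[w]])
    m <- if (w %in% wparts) {
      cm <- stats::contr.helmert(k)
      qr.Q(qr(cm))
    } else {
      matrix(1 / sqrt(k), k, 1)
    }
    basis <- kronecker(basis, m)
  }
  grp <- if (is.null(between)) {
    factor(rep(1, nrow(wide)))
  } else {
    g <- df[[between]][match(rownames(wide), as.character(df[[subject]]))]
    droplevels(factor(g))
  }
  # pooled covariance across groups
  p <- ncol(wide)
  Sp <- matrix(0, p, p)
  dfree <- 0
  for (g in levels(grp)) {
    X <- wide[grp == g, , drop = FALSE]
    if (nrow(X) < 2) next
    Sp <- Sp + stats::cov(X) * (nrow(X) - 1)
    dfree <- dfree + nrow(X) - 1
  }
  Sp <- Sp / dfree
  E <- t(basis) %*% Sp %*% basis
  lam <- Re(eigen(E, symmetric = TRUE, only.values = TRUE)$values)
  k <- nrow(E)
  if (k == 1) return(1)
  eps <- sum(lam)^2 / (k * sum(lam^2))
  min(1, max(1 / k, eps))
}

#' @export
print.erp_anova <- function(x, ...) {
  cat(sprintf("<erp_anova> %d subjects; effects:\n", x$n_subjects))
  t <- x$table
  for (i in seq_len(nrow(t))) {
    cat(sprintf("  %s: F(%g, %g) = %.2f; p = %.4g", t$effect[i],
                t$df_effect[i], t$df_error[i], t$F[i], t$p[i]))
    if (!is.na(t$gg_epsilon[i])) {
      cat(sprintf(" (GG eps = %.3f, p_GG = %.4g)", t$gg_epsilon[i], t$p_gg[i]))
    }
    cat(sprintf("; eta_p^2 = %.2f\n", t$partial_eta_sq[i]))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.erp_anova <- function(x, ...) x$table

#' @exportS3Method generics::glance
glance.erp_anova <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects,
                 n_effects = nrow(x$table),
                 n_sig_gg = sum(x$table$sig_gg))
}

#' Partial eta squared from an F statistic
#'
#' `F * df_effect / (F * df_effect + df_error)`, the effect-size convention
#' of the repeated-measures ANOVA literature.
#'
#' @param F F statistic (>= 0).
#' @param df_effect,df_error Degrees of freedom (> 0).
#' @return Partial eta squared in \[0, 1).
#' @examples
#' partial_eta_squared(67.8, 2, 44)  # 0.755
#' @export
partial_eta_squared <- function(F, df_effect, df_error) {
  stopifnot(all(F >= 0), all(df_effect > 0), all(df_error > 0))
  F * df_effect / (F * df_effect + df_error)
}

#' Bonferroni-corrected pairwise follow-up tests
#'
#' Runs paired (within-subject) or independent (between-group) two-tailed
#' t-tests for the requested comparisons and multiplies each raw p by the
#' number of comparisons, capped at 1. Zero-variance comparisons are
#' flagged as degenerate with `NA` p and a warning.
#'
#' @param table Long data frame with `subject`, a factor column and
#'   `value`.
#' @param factor_col Name of the factor whose levels are compared.
#' @param comparisons List of length-2 character vectors (level pairs);
#'   default all pairs.
#' @param paired Paired t-tests (within-subject) or independent.
#' @param value,subject Column names.
#' @return Tibble: level1, level2, t, df, p_raw, p_bonferroni, degenerate.
#' @export
pairwise_bonferroni <- function(table, factor_col, comparisons = NULL,
                                paired = TRUE, value = "value",
                                subject = "subject") {
  df <- as.data.frame(table)
  lev <- unique(as.character(df[[factor_col]]))
  if (is.null(comparisons)) {
    comparisons <- utils::combn(lev, 2, simplify = FALSE)
  }
  m <- length(comparisons)
  purrr::map_dfr(comparisons, function(cmp) {
    d1 <- df[df[[factor_col]] == cmp[1], ]
    d2 <- df[df[[factor_col]] == cmp[2], ]
    if (paired) {
      x <- d1[[value]][order(d1[[subject]])]
      y <- d2[[value]][order(d2[[subject]])]
      diffs <- x - y
      degen <- stats::sd(diffs) < .Machine$double.eps^0.5
    } else {
      x <- d1[[value]]; y <- d2[[value]]
      degen <- stats::sd(x) < .Machine$double.eps^0.5 &&
        stats::sd(y) < .Machine$double.eps^0.5
    }
    if (degen) {
      warning("degenerate (zero-variance) comparison: ",
              cmp[1], " vs ", cmp[2])
      return(tibble::tibble(level1 = cmp[1], level2 = cmp[2], t = NA_real_,
                            df = NA_real_, p_raw = NA_real_,
                            p_bonferroni = NA_real_, degenerate = TRUE))
    }
    tt <- stats::t.test(x, y, paired = paired, var.equal = !paired)
    tibble::tibble(level1 = cmp[1], level2 = cmp[2],
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p_raw = tt$p.value,
                   p_bonferroni = min(1, tt$p.value * m),
                   degenerate = FALSE)
  })
}

#' Pearson correlation with two-tailed p value
#'
#' Standard product-moment correlation; the p value comes from the exact t
#' transform. Constant input is an error (the correlation is undefined).
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return Tibble: r, n, t, df, p.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant input", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), n = length(x),
                 t = unname(ct$statistic), df = unname(ct$parameter),
                 p = ct$p.value)
}
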