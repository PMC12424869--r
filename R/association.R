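# Covariate-adjusted association of variant frequencies (or region burden /
# MAF) with quantitative traits (OLS) and disease indicators (logistic).
# The covariate model: age, sex, age x sex, age^2, rDNA copy number, 20
# genetic principal components, and one-hot sequencing-batch indicators
# (reference level dropped). Non-converged fits are flagged and excluded,
# never silently zeroed.

continuous_cov_cols <- function(pc_names)
  c("age", "age_sex", "age_sq", "rdna_cn", pc_names)

#' Build the association design matrix
#'
#' Columns: intercept, predictor, age, sex, age x sex, age^2, rDNA copy
#' number, the principal components, and batch one-hot columns with the
#' lexicographically first level as the dropped reference. With
#' `standardize = TRUE` (the logistic-path convention) the predictor and
#' all continuous covariates are z-scored.
#'
#' @param covariates data frame with columns `age`, `sex` (0/1), `rdna_cn`,
#'   `batch`, and principal-component columns matching `^PC[0-9]+$`.
#' @param predictor numeric vector (variant frequency, burden or MAF).
#' @param standardize z-score predictor and continuous covariates.
#' @return list: `X` (model matrix), `predictor_col` (its column index),
#'   `rows` (indices of complete cases used).
#' @export
build_design <- function(covariates, predictor, standardize = FALSE) {
  stopifnot(all(c("age", "sex", "rdna_cn", "batch") %in% names(covariates)),
            length(predictor) == nrow(covariates))
  pc_names <- grep("^PC[0-9]+$", names(covariates), value = TRUE)
  pc_names <- pc_names[order(as.integer(sub("PC", "", pc_names)))]
  df <- covariates
  df$age_sex <- df$age * df$sex
  df$age_sq <- df$age^2
  df$predictor <- predictor
  rows <- which(stats::complete.cases(
    df[c("predictor", "age", "sex", "age_sex", "age_sq", "rdna_cn",
         pc_names, "batch")]))
  df <- df[rows, , drop = FALSE]
  if (length(rows) == 0L) stop("no complete cases")
  if (stats::sd(df$predictor) == 0) stop("constant predictor")
  batch <- factor(df$batch, levels = sort(unique(as.character(df$batch))))
  bm <- if (nlevels(batch) > 1L) {
    m <- stats::model.matrix(~batch)[, -1L, drop = FALSE]
    colnames(m) <- paste0("batch_", levels(batch)[-1L])
    m
  } else NULL
  zscore <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x
  if (standardize) {
    df$predictor <- zscore(df$predictor)
    for (cc in continuous_cov_cols(pc_names)) df[[cc]] <- zscore(df[[cc]])
  }
  X <- cbind(`(Intercept)` = 1, predictor = df$predictor, age = df$age,
             sex = df$sex, age_sex = df$age_sex, age_sq = df$age_sq,
             rdna_cn = df$rdna_cn,
             as.matrix(df[pc_names]))
  if (!is.null(bm)) X <- cbind(X, bm)
  list(X = X, predictor_col = 2L, rows = rows)
}

association_row <- function(predictor_key, trait, model, beta = NA_real_,
                            se = NA_real_, p = NA_real_, n = NA_integer_,
                            converged = FALSE) {
  data.frame(predictor = predictor_key, trait = trait, model = model,
             beta = beta, se = se, p_value = p, n = n,
             converged = converged, stringsAsFactors = FALSE)
}

#' Ordinary least squares association fit
#'
#' Two-sided Wald test on the predictor column. Singular designs yield a
#' non-converged result rather than an error.
#'
#' @param y numeric trait values (rows matching `design$X`).
#' @param design a [build_design()] result.
#' @param predictor_key,trait labels carried into the result row.
#' @return one-row association data frame: `predictor`, `trait`, `model`,
#'   `beta`, `se`, `p_value`, `n`, `converged`.
#' @export
fit_linear <- function(y, design, predictor_key = "predictor",
                       trait = "trait") {
  X <- design$X
  ok <- !is.na(y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  n <- length(y); p <- ncol(X)
  if (n <= p)
    return(association_row(predictor_key, trait, "linear", n = n))
  fit <- stats::lm.fit(X, y)
  if (fit$rank < p)
    return(association_row(predictor_key, trait, "linear", n = n))
  sigma2 <- sum(fit$residuals^2) / (n - p)
  R <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
  R[lower.tri(R)] <- 0
  xtx_inv <- chol2inv(R)[order(fit$qr$pivot), order(fit$qr$pivot)]
  se <- sqrt(sigma2 * diag(xtx_inv))
  j <- design$predictor_col
  beta <- fit$coefficients[j]
  tval <- beta / se[j]
  association_row(predictor_key, trait, "linear", beta = unname(beta),
                  se = se[j],
                  p = 2 * stats::pt(-abs(tval), df = n - p),
                  n = n, converged = TRUE)
}

#' Maximum-likelihood logistic association fit
#'
#' Wald z test on the predictor column. IRLS non-convergence and complete
#' or quasi-complete separation (fitted probabilities at the 0/1 boundary)
#' are flagged non-converged and carry no estimate.
#'
#' @param y 0/1 case indicator.
#' @inheritParams fit_linear
#' @return one-row association data frame (see [fit_linear()]).
#' @export
fit_logistic <- function(y, design, predictor_key = "predictor",
                         trait = "trait") {
  X <- design$X
  ok <- !is.na(y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  n <- length(y); p <- ncol(X)
  if (length(unique(y)) < 2L || n <= p)
    return(association_row(predictor_key, trait, "logistic", n = n))
  separated <- FALSE
  fit <- withCallingHandlers(
    suppressWarnings(stats::glm.fit(X, y, family = stats::binomial())),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  eps <- 1e-10
  if (any(fit$fitted.values < eps) || any(fit$fitted.values > 1 - eps))
    separated <- TRUE
  if (!fit$converged || separated || fit$rank < p)
    return(association_row(predictor_key, trait, "logistic", n = n))
  R <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
  R[lower.tri(R)] <- 0
  cov <- chol2inv(R)[order(fit$qr$pivot), order(fit$qr$pivot)]
  se <- sqrt(diag(cov))
  j <- design$predictor_col
  beta <- fit$coefficients[j]
  z <- beta / se[j]
  association_row(predictor_key, trait, "logistic", beta = unname(beta),
                  se = se[j], p = 2 * stats::pnorm(-abs(z)), n = n,
                  converged = TRUE)
}

#' Association scan of predictors against traits
#'
#' Loops variants (columns of `predictors`) against traits, complete-case
#' per pair, and keeps the exclusion bookkeeping honest:
#' `attr(, "counts")` records attempted = reported + non-converged.
#'
#' @param predictors matrix participants x predictor keys (variant
#'   frequencies, burden or MAF columns).
#' @param traits data frame / matrix participants x traits (quantitative
#'   for `"linear"`, 0/1 indicators for `"logistic"`).
#' @param covariates covariate data frame (see [build_design()]).
#' @param model `"linear"` or `"logistic"`.
#' @param standardize z-score predictor and continuous covariates; default
#'   follows the model convention (TRUE for logistic, FALSE for linear).
#' @return association data frame, one row per converged (predictor,
#'   trait) pair; non-converged rows retained with `converged = FALSE`.
#' @export
associate <- function(predictors, traits, covariates,
                      model = c("linear", "logistic"),
                      standardize = NULL) {
  model <- match.arg(model)
  if (is.null(standardize)) standardize <- model == "logistic"
  traits <- as.data.frame(traits)
  rows <- list(); attempted <- 0L
  for (kk in colnames(predictors)) {
    x <- predictors[, kk]
    for (tr in colnames(traits)) {
      attempted <- attempted + 1L
      row <- tryCatch({
        keep <- !is.na(x)
        design <- build_design(covariates[keep, , drop = FALSE], x[keep],
                               standardize = standardize)
        yy <- traits[keep, tr][design$rows]
        if (model == "linear") fit_linear(yy, design, kk, tr)
        else fit_logistic(yy, design, kk, tr)
      }, error = function(e) association_row(kk, tr, model))
      rows[[length(rows) + 1L]] <- row
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "counts") <- c(attempted = attempted,
                           reported = sum(res$converged),
                           non_converged = sum(!res$converged))
  res
}

#' Disease-code filter by case count
#'
#' Keeps ICD10-style codes with at least `min_cases` cases. When
#' `min_cases` is not given it defaults to 30,000, or to
#' `ceiling(prevalence * cohort_n)` when a cohort size is supplied (the
#' same 6% prevalence cut at any scale).
#'
#' @param case_counts named integer vector, cases per code.
#' @param cohort_n optional cohort size for the scaled default.
#' @param min_cases explicit case threshold (inclusive).
#' @param prevalence prevalence used for the scaled default (0.06).
#' @return character vector of retained codes.
#' @export
filter_diseases <- function(case_counts, cohort_n = NULL, min_cases = NULL,
                            prevalence = 0.06) {
  if (is.null(min_cases))
    min_cases <- if (is.null(cohort_n)) 30000L else
      as.integer(ceiling(prevalence * cohort_n))
  as.character(names(case_counts)[case_counts >= min_cases])
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param n_variants number of variants tested.
#' @param n_independent_traits number of (independent) traits tested.
#' @return adjusted per-test threshold `alpha / (n_variants *
#'   n_independent_traits)`; compare with strict `<`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_variants = 1L,
                                 n_independent_traits = 1L) {
  stopifnot(n_variants >= 1L, n_independent_traits >= 1L)
  alpha / (n_variants * n_independent_traits)
}

#' Effective number of independent traits
#'
#' Default is the raw trait count (the most conservative Bonferroni
#' denominator). The `"eigen"` option computes a Li-Ji-style effective
#' number from the eigenvalues of the trait correlation matrix:
#' `sum(I(lambda >= 1) + (lambda - floor(lambda)))`.
#'
#' @param traits matrix / data frame participants x traits.
#' @param method `"raw"` (default) or `"eigen"`.
#' @return effective trait count (numeric).
#' @export
effective_trait_count <- function(traits, method = c("raw", "eigen")) {
  method <- match.arg(method)
  traits <- as.matrix(traits)
  if (method == "raw") return(ncol(traits))
  if (ncol(traits) < 2L || nrow(traits) < 3L)
    stop("eigen method needs >= 2 traits and >= 3 participants")
  lam <- eigen(stats::cor(traits, use = "pairwise.complete.obs"),
               symmetric = TRUE, only.values = TRUE)$values
  lam <- round(pmax(lam, 0), 8)  # guard the floor() against fp jitter
  sum(as.numeric(lam >= 1) + (lam - floor(lam)))
}

#' Expected/observed quantiles for a QQ plot, with genomic-control lambda
#'
#' @param p_values numeric p-values in (0, 1]; exact zeros are clamped to
#'   the smallest representable double with a warning.
#' @return data frame `expected`, `observed` (-log10 scale, ascending
#'   expected order) with attribute `lambda_gc` (median chi-square ratio).
#' @export
qq_data <- function(p_values) {
  p <- p_values[!is.na(p_values)]
  if (length(p) < 1L) stop("need at least one p-value")
  if (any(p == 0)) {
    warning("p-values of 0 clamped to machine minimum")
    p[p == 0] <- .Machine$double.xmin
  }
  m <- length(p)
  sp <- sort(p)
  out <- data.frame(expected = -log10((seq_len(m) - 0.5) / m),
                    observed = -log10(sp))
  attr(out, "lambda_gc") <-
    stats::median(stats::qchisq(1 - p, df = 1)) / stats::qchisq(0.5, df = 1)
  out
}

#' Write association results as TSV
#' @param results data frame from [associate()].
#' @param path output TSV path.
#' @param threshold optional Bonferroni threshold; adds a `significant`
#'   column (strict `p < threshold`).
#' @return `path`, invisibly.
#' @export
write_association_tsv <- function(results, path, threshold = NULL) {
  if (!is.null(threshold))
    results$significant <- results$converged & !is.na(results$p_value) &
      results$p_value < threshold
  write_tsv_commented(results, path,
    "association results; non-converged rows carry no estimates")
}
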