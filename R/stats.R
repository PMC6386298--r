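#' Pearson correlation with two-tailed p-value
#'
#' Product-moment correlation; the p-value comes from the exact t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`, non-degenerate.
#' @return list with `r`, `p` and `n`.
#' @examples
#' pearson(c(1, 2, 3, 4), c(1, 3, 2, 4))  # r = 0.8
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("fewer than 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in x or y")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Intraclass correlation coefficient for two-grader agreement
#'
#' Single-measure ICC with F-based 95% confidence interval, computed from
#' the two-way ANOVA mean squares. The default is the two-way
#' random-effects, absolute-agreement form ICC(2,1) (both graders regarded
#' as sampled from a population of raters and systematic grader offsets
#' counted as disagreement); ICC(3,1) (two-way mixed, consistency) is
#' available as an alternative.
#'
#' @param grader_a,grader_b paired measurements (same eyes, same order),
#'   `n >= 5`.
#' @param model `"ICC2"` (default, absolute agreement) or `"ICC3"`
#'   (consistency).
#' @param conf confidence level (default 0.95).
#' @return list with `icc`, `ci` (length-2), `model` and `n`.
#' @export
icc <- function(grader_a, grader_b, model = c("ICC2", "ICC3"), conf = 0.95) {
  model <- match.arg(model)
  if (length(grader_a) != length(grader_b))
    stop("grader vectors have mismatched lengths")
  ok <- is.finite(grader_a) & is.finite(grader_b)
  a <- grader_a[ok]; b <- grader_b[ok]
  ns <- length(a)
  if (ns < 5) stop("at least 5 paired measurements are required")
  k <- 2
  # two-way mean squares, one observation per cell (subjects x raters)
  y <- cbind(a, b)
  grand <- mean(y)
  msr <- k * sum((rowMeans(y) - grand)^2) / (ns - 1)
  msc <- ns * sum((colMeans(y) - grand)^2) / (k - 1)
  sse <- sum((y - outer(rowMeans(y), rep(1, k)) -
                outer(rep(1, ns), colMeans(y)) + grand)^2)
  mse <- sse / ((ns - 1) * (k - 1))
  alpha <- 1 - conf
  if (model == "ICC2") {
    coeff <- (msr - mse) / (msr + (k - 1) * mse + (k / ns) * (msc - mse))
    # McGraw & Wong F-based interval for ICC(A,1)
    aa <- (k * coeff) / (ns * (1 - coeff))
    bb <- 1 + (k * coeff * (ns - 1)) / (ns * (1 - coeff))
    v <- (aa * msc + bb * mse)^2 /
      ((aa * msc)^2 / (k - 1) + (bb * mse)^2 / ((ns - 1) * (k - 1)))
    f_l <- qf(1 - alpha / 2, ns - 1, v)
    f_u <- qf(1 - alpha / 2, v, ns - 1)
    lo <- ns * (msr - f_l * mse) /
      (f_l * (k * msc + (k * ns - k - ns) * mse) + ns * msr)
    hi <- ns * (f_u * msr - mse) /
      (k * msc + (k * ns - k - ns) * mse + ns * f_u * msr)
  } else {
    coeff <- (msr - mse) / (msr + (k - 1) * mse)
    f_obs <- msr / mse
    f_l <- f_obs / qf(1 - alpha / 2, ns - 1, (ns - 1) * (k - 1))
    f_u <- f_obs * qf(1 - alpha / 2, (ns - 1) * (k - 1), ns - 1)
    lo <- (f_l - 1) / (f_l + k - 1)
    hi <- (f_u - 1) / (f_u + k - 1)
  }
  list(icc = coeff, ci = c(lo, hi), model = model, n = ns)
}

#' Gaussian GEE with exchangeable working correlation
#'
#' Marginal linear regression for clustered observations (eyes within
#' patients), fit by iterated generalized least squares: the exchangeable
#' intra-cluster correlation `alpha` and scale are re-estimated from the
#' Pearson residuals at each step and the coefficients re-solved until
#' convergence. Inference uses the robust (sandwich) covariance estimator,
#' so standard errors are valid even if the working correlation is wrong.
#' With all clusters of size one there are no residual pairs, `alpha` is 0,
#' and the estimates coincide with ordinary least squares.
#'
#' With few clusters the plain sandwich underestimates variability and the
#' Wald test rejects too often; the default therefore applies the
#' Mancl–DeRouen bias correction to the meat of the sandwich and refers the
#' statistic to a t distribution on `clusters - parameters` degrees of
#' freedom, which restores near-nominal type-I error for cohorts of a few
#' dozen patients. `se = "robust"` gives the uncorrected sandwich with a
#' normal reference (the convention of the classic GEE software); point
#' estimates are identical either way.
#'
#' @param formula model formula (Gaussian family, identity link).
#' @param data data.frame with all model variables.
#' @param id cluster identifier: a column name or a vector of length
#'   `nrow(data)`.
#' @param se `"bias-corrected"` (Mancl–DeRouen meat, t reference; default)
#'   or `"robust"` (plain sandwich, normal reference).
#' @param tol,max_iter convergence tolerance on coefficients and iteration
#'   cap.
#' @return object of class `gee_fit`: `coefficients`, `robust_se` (of the
#'   chosen estimator), `z`, `p` (two-sided), `vcov`, `alpha`, `scale`,
#'   `df` (`Inf` for the normal reference), `se_method`, `n_clusters`,
#'   `n_obs`, `formula`.
#' @export
gee_fit <- function(formula, data, id, se = c("bias-corrected", "robust"),
                    tol = 1e-10, max_iter = 50) {
  se <- match.arg(se)
  if (is.character(id) && length(id) == 1L) id <- data[[id]]
  stopifnot(length(id) == nrow(data))
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  p <- ncol(X)
  if (qr(X)$rank < p) {
    stop("singular design matrix; collinear columns: ",
         paste(colnames(X), collapse = ", "))
  }
  idx <- split(seq_along(y), as.character(id))
  n_cl <- length(idx)
  if (n_cl < 2) stop("GEE requires at least 2 clusters")
  n <- length(y)
  beta <- qr.solve(X, y)  # OLS start
  alpha <- 0
  for (iter in seq_len(max_iter)) {
    r <- as.numeric(y - X %*% beta)
    phi <- sum(r^2) / (n - p)
    npairs <- sum(vapply(idx, function(ii) {
      m <- length(ii); m * (m - 1) / 2
    }, 0.0))
    if (npairs > p) {
      cross <- sum(vapply(idx, function(ii) {
        ri <- r[ii]
        (sum(ri)^2 - sum(ri^2)) / 2
      }, 0.0))
      alpha <- cross / (phi * (npairs - p))
      max_m <- max(lengths(idx))
      alpha <- max(min(alpha, 0.99), -1 / (max_m - 1) + 1e-6)
    } else {
      alpha <- 0
    }
    A <- matrix(0, p, p)
    bvec <- numeric(p)
    for (ii in idx) {
      m <- length(ii)
      Ri <- matrix(alpha, m, m); diag(Ri) <- 1
      Xi <- X[ii, , drop = FALSE]
      W <- solve(Ri, cbind(Xi, y[ii]))
      A <- A + crossprod(Xi, W[, seq_len(p), drop = FALSE])
      bvec <- bvec + crossprod(Xi, W[, p + 1L])
    }
    beta_new <- solve(A, bvec)
    done <- max(abs(beta_new - beta)) < tol * (1 + max(abs(beta)))
    beta <- as.numeric(beta_new)
    if (done) break
  }
  # sandwich covariance (phi cancels between bread and meat); with the
  # Mancl-DeRouen option the cluster residuals are inflated by
  # (I - H_i)^{-1}, H_i the cluster leverage, before entering the meat
  r <- as.numeric(y - X %*% beta)
  M <- matrix(0, p, p)
  for (ii in idx) {
    Ri <- matrix(alpha, length(ii), length(ii)); diag(Ri) <- 1
    Xi <- X[ii, , drop = FALSE]
    M <- M + crossprod(Xi, solve(Ri, Xi))
  }
  Minv <- solve(M)
  B <- matrix(0, p, p)
  for (ii in idx) {
    m <- length(ii)
    Ri <- matrix(alpha, m, m); diag(Ri) <- 1
    Xi <- X[ii, , drop = FALSE]
    Wi <- solve(Ri)
    ei <- r[ii]
    if (se == "bias-corrected") {
      # (I - H_i) can be numerically singular when one cluster dominates a
      # very small fit; fall back to the uncorrected residual there
      Hi <- Xi %*% Minv %*% crossprod(Xi, Wi)
      ei <- tryCatch(solve(diag(m) - Hi, ei), error = function(e) ei)
    }
    u <- crossprod(Xi, Wi %*% ei)
    B <- B + tcrossprod(u)
  }
  V <- Minv %*% B %*% Minv
  se_vec <- sqrt(diag(V))
  z <- beta / se_vec
  df <- if (se == "bias-corrected") max(n_cl - p, 1L) else Inf
  structure(list(
    coefficients = stats::setNames(beta, colnames(X)),
    robust_se = stats::setNames(se_vec, colnames(X)),
    z = z,
    p = 2 * stats::pt(-abs(z), df = df),
    vcov = V,
    alpha = alpha,
    scale = sum(r^2) / (n - p),
    df = df,
    se_method = se,
    n_clusters = n_cl,
    n_obs = n,
    formula = formula
  ), class = "gee_fit")
}

#' @export
print.gee_fit <- function(x, ...) {
  cat("Gaussian GEE (identity link, exchangeable working correlation)\n")
  cat(sprintf("  %d observations in %d clusters; alpha = %.3f; %s SE\n",
              x$n_obs, x$n_clusters, x$alpha, x$se_method))
  tab <- data.frame(B = x$coefficients, SE = x$robust_se, p = x$p)
  print(round(tab, 4))
  invisible(x)
}

#' Univariable GEE screen followed by a multivariable model
#'
#' Fits one Gaussian GEE per candidate covariate with the outcome as
#' dependent variable and patients as clusters; candidates significant at
#' `alpha_enter` then enter a single multivariable GEE. Mirrors the usual
#' screen-then-model reporting layout (covariate, univariable B (SE), p,
#' multivariable B (SE), p).
#'
#' @param table data.frame of eye records (one row per eye).
#' @param candidates character vector of covariate column names.
#' @param outcome outcome column (default `"yGR"`).
#' @param cluster cluster column (default `"patient_id"`).
#' @param alpha_enter significance gate for multivariable entry
#'   (default 0.05).
#' @param se standard-error estimator passed to [gee_fit()].
#' @return object of class `gee_screen`: `univariable` (data.frame),
#'   `multivariable` (data.frame or `NULL`), `selected` (screened-in
#'   candidates), `entered` (those actually in the joint model), `dropped`
#'   (screened-in but aliased by stronger covariates, e.g. dFV when FV_500
#'   and FV_1000 are both in) and `note` (character).
#' @export
gee_screen_and_model <- function(table, candidates, outcome = "yGR",
                                 cluster = "patient_id", alpha_enter = 0.05,
                                 se = c("bias-corrected", "robust")) {
  se <- match.arg(se)
  stopifnot(is.data.frame(table), all(candidates %in% names(table)),
            outcome %in% names(table), cluster %in% names(table))
  if (anyNA(table[, c(outcome, candidates)]))
    stop("missing values in modeled columns")
  uni <- do.call(rbind, lapply(candidates, function(v) {
    f <- stats::as.formula(paste(outcome, "~", v))
    fit <- gee_fit(f, table, id = cluster, se = se)
    data.frame(covariate = v,
               B = unname(fit$coefficients[v]),
               SE = unname(fit$robust_se[v]),
               p = unname(fit$p[which(names(fit$coefficients) == v)]),
               stringsAsFactors = FALSE)
  }))
  selected <- uni$covariate[uni$p < alpha_enter]
  if (length(selected) == 0L) {
    return(structure(list(
      univariable = uni, multivariable = NULL, selected = character(),
      note = "no candidate significant in the univariable screen; multivariable stage skipped"
    ), class = "gee_screen"))
  }
  # exact linear dependencies among the selected covariates (e.g. dFV =
  # FV_500 - FV_1000 when all three pass the screen) make the joint design
  # singular; keep covariates in order of univariable strength and drop any
  # that are aliased by those already in
  ord <- selected[order(uni$p[match(selected, uni$covariate)])]
  entered <- character()
  for (v in ord) {
    X <- cbind(1, as.matrix(table[, c(entered, v), drop = FALSE]))
    if (qr(X)$rank == ncol(X)) entered <- c(entered, v)
  }
  dropped <- setdiff(selected, entered)
  entered <- selected[selected %in% entered]  # restore candidate order
  f <- stats::as.formula(paste(outcome, "~", paste(entered, collapse = " + ")))
  fit <- gee_fit(f, table, id = cluster, se = se)
  keep <- match(entered, names(fit$coefficients))
  multi <- data.frame(covariate = entered,
                      B = unname(fit$coefficients[keep]),
                      SE = unname(fit$robust_se[keep]),
                      p = unname(fit$p[keep]),
                      stringsAsFactors = FALSE)
  note <- sprintf("%d candidate(s) entered the multivariable model",
                  length(entered))
  if (length(dropped))
    note <- paste0(note, "; dropped as collinear with stronger covariates: ",
                   paste(dropped, collapse = ", "))
  structure(list(univariable = uni, multivariable = multi,
                 selected = selected, entered = entered, dropped = dropped,
                 note = note),
            class = "gee_screen")
}

#' @export
print.gee_screen <- function(x, ...) {
  cat("Univariable GEE screen (outcome ~ each covariate):\n")
  u <- x$univariable
  u$`B (SE)` <- sprintf("%.3f (%.4f)", u$B, u$SE)
  print(u[, c("covariate", "B (SE)", "p")], row.names = FALSE, digits = 3)
  if (is.null(x$multivariable)) {
    cat(x$note, "\n")
  } else {
    cat("Multivariable GEE:\n")
    m <- x$multivariable
    m$`B (SE)` <- sprintf("%.3f (%.4f)", m$B, m$SE)
    print(m[, c("covariate", "B (SE)", "p")], row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Flatten a GEE screen into a report table
#'
#' One row per candidate with univariable and (where entered) multivariable
#' coefficient, SE and p — the usual published layout.
#'
#' @param screen a `gee_screen` from [gee_screen_and_model()].
#' @return data.frame with columns `covariate`, `uni_B`, `uni_SE`, `uni_p`,
#'   `multi_B`, `multi_SE`, `multi_p`.
#' @export
format_regression_table <- function(screen) {
  stopifnot(inherits(screen, "gee_screen"))
  u <- screen$univariable
  out <- data.frame(covariate = u$covariate,
                    uni_B = u$B, uni_SE = u$SE, uni_p = u$p,
                    multi_B = NA_real_, multi_SE = NA_real_,
                    multi_p = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(screen$multivariable)) {
    m <- screen$multivariable
    i <- match(m$covariate, out$covariate)
    out$multi_B[i] <- m$B
    out$multi_SE[i] <- m$SE
    out$multi_p[i] <- m$p
  }
  out
}

#' Recompute cohort statistics from a per-eye study database
#'
#' Given a per-eye table with the study's column layout (one row per eye:
#' patient and eye identifiers, baseline and follow-up GA areas, follow-up
#' time, the flow-void percentages and the fovea distance, plus age),
#' recomputes the derived quantities and the full statistical report:
#' yGR and dFV per eye, cohort means/SDs, Pearson correlations of yGR with
#' each flow-void measure, and the univariable-then-multivariable GEE
#' analysis. Intended for re-analysis of a published per-eye database; the
#' table is an input, not something this package can reconstruct from
#' summary statistics.
#'
#' @param eyes data.frame with columns `patient_id`, `eye_id`, `GA_I`,
#'   `GA_II`, `FU`, `FV_OUT`, `FV_500`, `FV_1000`, `age`, `fovea_dist`
#'   (column `dFV` and `yGR` are recomputed if absent).
#' @return list with `eyes` (augmented table), `summary` (named means/SDs),
#'   `correlations` (data.frame) and `gee` (a `gee_screen`).
#' @export
replicate_study_stats <- function(eyes) {
  need <- c("patient_id", "GA_I", "GA_II", "FU", "FV_OUT", "FV_500",
            "FV_1000", "age", "fovea_dist")
  missing_cols <- setdiff(need, names(eyes))
  if (length(missing_cols))
    stop("per-eye table lacks columns: ", paste(missing_cols, collapse = ", "))
  eyes$yGR <- compute_ygr(eyes$GA_I, eyes$GA_II, eyes$FU)
  eyes$dFV <- eyes$FV_500 - eyes$FV_1000
  summ <- c(
    n_eyes = nrow(eyes), n_patients = length(unique(eyes$patient_id)),
    mean_yGR = mean(eyes$yGR), sd_yGR = sd(eyes$yGR),
    mean_FV_OUT = mean(eyes$FV_OUT), sd_FV_OUT = sd(eyes$FV_OUT),
    mean_FV_500 = mean(eyes$FV_500), sd_FV_500 = sd(eyes$FV_500),
    mean_FV_1000 = mean(eyes$FV_1000), sd_FV_1000 = sd(eyes$FV_1000),
    mean_dFV = mean(eyes$dFV), sd_dFV = sd(eyes$dFV)
  )
  fvs <- c("FV_OUT", "FV_500", "FV_1000", "dFV")
  correlations <- do.call(rbind, lapply(fvs, function(v) {
    pr <- pearson(eyes[[v]], eyes$yGR)
    data.frame(measure = v, r = pr$r, p = pr$p, stringsAsFactors = FALSE)
  }))
  screen <- gee_screen_and_model(
    eyes, candidates = c("age", "GA_I", "fovea_dist", "FV_500", "FV_1000",
                         "FV_OUT", "dFV"))
  list(eyes = eyes, summary = summ, correlations = correlations, gee = screen)
}
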