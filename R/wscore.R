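# Normative design matrix. Column order is fixed by the descriptor so a
# fitted model can reject covariate layouts it has not seen.
normative_design <- function(records, covariates, levels = NULL) {
  cols <- list(intercept = rep(1, nrow(records)))
  lv <- list()
  for (cv in covariates) {
    if (cv %in% c("age", "icv")) {
      cols[[cv]] <- records[[cv]]
    } else {
      obs <- if (!is.null(levels[[cv]])) levels[[cv]] else sort(unique(records[[cv]]))
      lv[[cv]] <- obs
      unseen <- setdiff(unique(records[[cv]]), obs)
      if (length(unseen))
        stop(sprintf("unseen level(s) of %s: %s", cv, paste(unseen, collapse = ", ")))
      for (l in obs[-1])  # one-hot, first level is the reference
        cols[[paste(cv, l, sep = ".")]] <- as.numeric(records[[cv]] == l)
    }
  }
  C <- do.call(cbind, cols)
  colnames(C) <- names(cols)
  list(C = C, levels = lv)
}

#' Fit a per-feature normative regression on normal controls
#'
#' For every feature an ordinary least-squares regression on the covariate
#' design (intercept, age, sex, ICV, field strength, and optionally site and
#' scanner, one-hot with first-level reference) is fitted using only NC rows.
#' The residual scale `sigma` uses the (n - p) denominator, and is floored at
#' `1e-8` times the feature's SD to guard degenerate features.
#'
#' @param nc_table raw [feature_table()] restricted to NC rows.
#' @param nc_records matching [subject_records()] (all diagnosis `"NC"`).
#' @param covariates character vector among `age`, `sex`, `icv`,
#'   `field_strength`, `site`, `scanner`.
#' @return object of class `normative_model`: coefficient matrix `beta`
#'   (design columns x features), `sigma` per feature, the design descriptor.
#' @export
fit_normative <- function(nc_table, nc_records,
                          covariates = c("age", "sex", "icv", "field_strength",
                                         "site", "scanner")) {
  stopifnot(all(nc_records$diagnosis == "NC"))
  des <- normative_design(nc_records, covariates)
  C <- des$C
  n <- nrow(C); p <- ncol(C)
  if (n <= p) stop(sprintf("need more than %d NC rows to fit %d design columns", p, p))
  qr_C <- qr(C)
  if (qr_C$rank < p) {
    bad <- colnames(C)[qr_C$pivot[(qr_C$rank + 1):p]]
    stop("rank-deficient normative design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  X <- nc_table$X
  beta <- qr.coef(qr_C, X)
  resid <- X - C %*% beta
  sigma <- sqrt(colSums(resid^2) / (n - p))
  floor_ <- 1e-8 * apply(X, 2, stats::sd)
  sigma <- pmax(sigma, floor_, 1e-12)
  structure(list(beta = beta, sigma = sigma, covariates = covariates,
                 design_columns = colnames(C), levels = des$levels,
                 n = n, p = p),
            class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf("<normative_model> %d features, design: %s (n = %d)\n",
              length(x$sigma), paste(x$design_columns, collapse = ", "), x$n))
  invisible(x)
}

#' Convert raw features to w-scores
#'
#' `w = (observed - predicted) / sigma` per feature, where the prediction
#' comes from the NC-fitted normative model. Unseen categorical levels are an
#' error (refit or pool upstream).
#'
#' @param model a [fit_normative()] model.
#' @param table raw [feature_table()].
#' @param records matching [subject_records()] (any diagnosis).
#' @return a [feature_table()] with `kind = "wscore"`.
#' @export
compute_wscore <- function(model, table, records) {
  stopifnot(inherits(model, "normative_model"), table$kind == "raw")
  des <- normative_design(records, model$covariates, levels = model$levels)
  if (!identical(colnames(des$C), model$design_columns))
    stop("covariate design mismatch with the fitted model")
  W <- (table$X - des$C %*% model$beta) / rep(model$sigma, each = nrow(table$X))
  colnames(W) <- colnames(table$X)
  feature_table(table$ids, W, table$sets, kind = "wscore")
}

#' Serialize / read a normative model as CSV
#'
#' Long format: feature, coefficient name (or `"sigma"`), value.
#' @param model a `normative_model`.
#' @param path CSV path.
#' @return invisibly `path` (write) or a `normative_model` (read); the read
#'   model carries no categorical level registry and must only be applied to
#'   data with the same design columns.
#' @export
write_normative_model <- function(model, path) {
  feat <- colnames(model$beta)
  if (is.null(feat)) feat <- sprintf("f%d", seq_len(ncol(model$beta)))
  long <- data.table::data.table(
    feature = rep(feat, each = nrow(model$beta) + 1L),
    coefficient = rep(c(rownames(model$beta), "sigma"), times = length(feat)),
    value = as.numeric(rbind(model$beta, model$sigma)))
  data.table::fwrite(long, path)
  invisible(path)
}

#' @rdname write_normative_model
#' @export
read_normative_model <- function(path) {
  df <- data.table::fread(path)
  feats <- unique(df$feature)
  coefs <- setdiff(unique(df$coefficient), "sigma")
  beta <- matrix(NA_real_, length(coefs), length(feats),
                 dimnames = list(coefs, feats))
  for (i in seq_len(nrow(df))) {
    if (df$coefficient[i] != "sigma")
      beta[df$coefficient[i], df$feature[i]] <- df$value[i]
  }
  sigma <- df$value[df$coefficient == "sigma"]
  names(sigma) <- df$feature[df$coefficient == "sigma"]
  sigma <- sigma[feats]
  structure(list(beta = beta, sigma = sigma, covariates = NULL,
                 design_columns = coefs, levels = NULL,
                 n = NA_integer_, p = length(coefs)),
            class = "normative_model")
}

#' Per-feature group comparison on w-scores
#'
#' Welch (unequal-variance) two-sample t-test for every feature between two
#' diagnostic groups, with Benjamini-Hochberg false-discovery-rate control.
#'
#' @param wtable w-score [feature_table()].
#' @param records matching [subject_records()].
#' @param group_a,group_b diagnosis labels to compare.
#' @param q FDR level (default 0.05).
#' @return data.frame: feature, t, p, p_adj, significant.
#' @export
groupwise_feature_tests <- function(wtable, records, group_a, group_b, q = 0.05) {
  records <- align_records(records, wtable)
  A <- wtable$X[records$diagnosis == group_a, , drop = FALSE]
  B <- wtable$X[records$diagnosis == group_b, , drop = FALSE]
  if (nrow(A) < 2 || nrow(B) < 2) stop("each group needs at least 2 rows")
  na <- nrow(A); nb <- nrow(B)
  ma <- colMeans(A); mb <- colMeans(B)
  va <- colSums(sweep(A, 2, ma)^2) / (na - 1)
  vb <- colSums(sweep(B, 2, mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- ifelse(se2 > 0, (ma - mb) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)), 1)
  p <- 2 * stats::pt(-abs(t), df)
  p[se2 == 0] <- 1
  p_adj <- stats::p.adjust(p, method = "BH")
  data.frame(feature = colnames(wtable$X), t = t, p = p, p_adj = p_adj,
             significant = p_adj <= q, row.names = NULL,
             stringsAsFactors = FALSE)
}
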