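# Gaussian linear discriminant classifier with a shared (pooled)
# covariance matrix and a fixed fibrous-tissue prior.

#' Classifier configuration
#'
#' @param fibrous_prior Prior probability assigned to fibrous tissue
#'   (default 0.55); the remaining mass is distributed over the other
#'   classes proportionally to their training-set frequencies.
#' @param covariance_regularization Shrinkage coefficient `lambda`: the
#'   pooled covariance becomes `(1 - lambda) * S + lambda * diag(diag(S))`.
#'   Default `1e-4`; `0` disables regularization.
#' @param standardize Standardize features (z-score over the training set)
#'   before fitting; default `FALSE`.
#' @param postprocess_window Side of the square neighbourhood used when
#'   relabelling isolated pixels (default 3).
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(fibrous_prior = 0.55,
                              covariance_regularization = 1e-4,
                              standardize = FALSE,
                              postprocess_window = 3L) {
  check_number(fibrous_prior, "fibrous_prior", min = 0, max = 1,
               strict_min = TRUE, strict_max = TRUE)
  check_number(covariance_regularization, "covariance_regularization",
               min = 0, max = 1)
  pw <- check_count(postprocess_window, "postprocess_window", min = 3L)
  if (pw %% 2L == 0L) abort("`postprocess_window` must be odd.")
  structure(list(fibrous_prior = fibrous_prior,
                 covariance_regularization = covariance_regularization,
                 standardize = isTRUE(standardize),
                 postprocess_window = pw),
            class = "classifier_config")
}

#' Class priors with a fixed fibrous prior
#'
#' Fibrous tissue receives exactly `fibrous_prior`; every other class
#' present in training receives `(1 - fibrous_prior)` times its share of
#' the non-fibrous training pixels, so the priors sum to one.  Absent
#' classes get prior 0.  If no non-fibrous pixels exist, fibrous gets
#' prior 1 with a warning.
#'
#' @param counts Named vector of training pixel counts per class.
#' @param fibrous_prior Prior for fibrous tissue (default 0.55).
#' @return Named numeric vector of priors over the classes in `counts`.
#' @export
#' @examples
#' compute_priors(c(fibrous = 700, lipid = 100, calcification = 100,
#'                  loose_matrix = 100))
compute_priors <- function(counts, fibrous_prior = 0.55) {
  if (is.null(names(counts)) || !"fibrous" %in% names(counts) ||
      counts[["fibrous"]] <= 0) {
    abort("`counts` must be named and include a positive fibrous count.")
  }
  check_number(fibrous_prior, "fibrous_prior", min = 0, max = 1,
               strict_min = TRUE, strict_max = TRUE)
  other <- counts[setdiff(names(counts), "fibrous")]
  pri <- setNames(numeric(length(counts)), names(counts))
  if (length(other) == 0 || sum(other) == 0) {
    warn("only fibrous tissue present in training; its prior is set to 1.")
    pri["fibrous"] <- 1
    return(pri)
  }
  pri["fibrous"] <- fibrous_prior
  pri[names(other)] <- (1 - fibrous_prior) * other / sum(other)
  pri
}

# Build an LDC model from per-class sufficient statistics:
#   n[c], sums[[c]] (column sums), cross[[c]] (X'X), over classes with n>0.
# Shared code path for train_ldc() and the cross-validation folds.
ldc_from_stats <- function(n, sums, cross, feature_names, config) {
  keep <- names(n)[n > 0]
  if (!"fibrous" %in% keep) {
    abort("training set lacks fibrous tissue; cannot fit the classifier.")
  }
  if (length(keep) < 2 || sum(n[keep] >= 2) < 2) {
    abort("need at least 2 classes with at least 2 training pixels each.")
  }
  p <- length(feature_names)
  means <- matrix(0, length(keep), p, dimnames = list(keep, feature_names))
  scatter <- matrix(0, p, p)
  for (cls in keep) {
    mu <- sums[[cls]] / n[[cls]]
    means[cls, ] <- mu
    scatter <- scatter + cross[[cls]] - n[[cls]] * tcrossprod(mu)
  }
  N <- sum(n[keep]); K <- length(keep)
  S <- scatter / (N - K)
  lam <- config$covariance_regularization
  d <- diag(S)
  if (all(d == 0)) {
    abort("every feature has zero within-class variance; cannot fit a covariance.")
  }
  # shrink toward the diagonal, flooring degenerate (zero-variance)
  # entries so that noise-free training data stays invertible
  d_floor <- pmax(d, 0.01 * mean(d))
  S_reg <- (1 - lam) * S + lam * diag(d_floor, p)
  ch <- tryCatch(chol(S_reg), error = function(e) NULL)
  if (is.null(ch) || rcond_from_chol(ch) < 1e-13) {
    abort(paste("pooled covariance is singular; increase",
                "`covariance_regularization` (shrinkage toward the diagonal)."))
  }
  priors <- compute_priors(setNames(as.numeric(n[keep]), keep),
                           config$fibrous_prior)
  structure(list(classes = keep, means = means, covariance = S_reg,
                 chol = ch, priors = priors, counts = n[keep],
                 feature_names = feature_names, config = config,
                 n_train = N),
            class = "plaque_ldc")
}

# split a feature tibble into matrix + labels + provenance
feature_parts <- function(features) {
  fn <- attr(features, "feature_names") %||% setdiff(
    names(features),
    c("patient_id", "scan_session", "slice_index", "row", "col", "label"))
  list(X = as.matrix(features[, fn, drop = FALSE]),
       label = features$label, fn = fn)
}

# per-class sufficient statistics of one labelled feature matrix
class_stats <- function(X, label) {
  codes <- sort(unique(label[label > 0]))
  n <- setNames(numeric(0), character(0))
  sums <- list(); cross <- list()
  for (cd in codes) {
    cls <- class_name(cd)
    sel <- label == cd
    Xc <- X[sel, , drop = FALSE]
    n[[cls]] <- nrow(Xc)
    sums[[cls]] <- colSums(Xc)
    cross[[cls]] <- crossprod(Xc)
  }
  list(n = n, sums = sums, cross = cross)
}

#' Train the linear discriminant classifier
#'
#' Each class is modelled as a multivariate Gaussian with its own mean and
#' a pooled (shared) covariance, estimated from the within-class scatter
#' and optionally shrunk toward its diagonal.  Priors follow
#' [compute_priors()]: fibrous fixed (default 0.55), the rest by training
#' frequency.
#'
#' @param features A labelled feature tibble from [build_feature_matrix()]
#'   (`label` = integer class codes; 0/`NA` rows are dropped).
#' @param config A [classifier_config()].
#' @return An object of class `plaque_ldc` with `tidy()` and `glance()`
#'   methods.
#' @export
train_ldc <- function(features, config = classifier_config()) {
  fp <- feature_parts(features)
  keep <- !is.na(fp$label) & fp$label > 0
  X <- fp$X[keep, , drop = FALSE]
  label <- fp$label[keep]
  if (config$standardize) {
    ctr <- colMeans(X); scl <- apply(X, 2, sd)
    scl[scl == 0] <- 1
    X <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  }
  st <- class_stats(X, label)
  model <- ldc_from_stats(st$n, st$sums, st$cross, fp$fn, config)
  if (config$standardize) {
    model$standardize <- list(center = ctr, scale = scl)
  }
  model
}

#' @export
print.plaque_ldc <- function(x, ...) {
  cat(sprintf("<plaque_ldc> %d classes, %d features, %d training pixels\n",
              length(x$classes), length(x$feature_names), x$n_train))
  cat("  priors:", paste(sprintf("%s %.3f", x$classes, x$priors[x$classes]),
                         collapse = ", "), "\n")
  invisible(x)
}

#' @rdname train_ldc
#' @param x A `plaque_ldc` model.
#' @param ... Unused.
#' @export
tidy.plaque_ldc <- function(x, ...) {
  tibble(class = x$classes,
         n_train = as.numeric(x$counts[x$classes]),
         prior = as.numeric(x$priors[x$classes])) |>
    dplyr::bind_cols(as_tibble(x$means))
}

#' @rdname train_ldc
#' @export
glance.plaque_ldc <- function(x, ...) {
  tibble(n_classes = length(x$classes),
         n_features = length(x$feature_names),
         n_train = x$n_train,
         fibrous_prior = x$config$fibrous_prior,
         shrinkage = x$config$covariance_regularization)
}

#' Classify wall pixels by maximum posterior
#'
#' Posterior probabilities are computed from the shared-covariance Gaussian
#' model: `posterior(c | x) proportional to N(x; mu_c, Sigma) * prior_c`,
#' evaluated via the linear discriminant functions (the shared quadratic
#' term cancels).  The label is the posterior argmax; exact ties are broken
#' by the fixed class order of [tissue_classes()].
#'
#' @param model A `plaque_ldc` from [train_ldc()].
#' @param features Feature tibble (or matrix with matching columns).
#' @return A tibble with `.class` (class name), `.code` (integer code) and
#'   one posterior column per model class; posteriors sum to 1 per row.
#' @export
classify_pixels <- function(model, features) {
  X <- if (is.matrix(features)) features else feature_parts(features)$X
  if (!identical(colnames(X), model$feature_names)) {
    if (!all(model$feature_names %in% colnames(X))) {
      abort("feature schema does not match the model's feature names.")
    }
    X <- X[, model$feature_names, drop = FALSE]
  }
  if (!is.null(model$standardize)) {
    X <- sweep(sweep(X, 2, model$standardize$center), 2,
               model$standardize$scale, "/")
  }
  # discriminant: x' S^-1 mu_c - mu_c' S^-1 mu_c / 2 + log prior_c
  Minv_mu <- backsolve(model$chol, forwardsolve(t(model$chol), t(model$means)))
  lin <- X %*% Minv_mu                      # n x K
  const <- -0.5 * colSums(t(model$means) * Minv_mu) +
    log(ifelse(model$priors[model$classes] > 0,
               model$priors[model$classes], .Machine$double.xmin))
  scores <- sweep(lin, 2, const, "+")
  scores[, model$priors[model$classes] == 0] <- -Inf
  m <- apply(scores, 1, max)
  post <- exp(scores - m)
  post <- post / rowSums(post)
  colnames(post) <- model$classes
  # argmax with ties broken by canonical class order
  ord <- order(match(model$classes, component_names()))
  post_ord <- post[, ord, drop = FALSE]
  win <- max.col(post_ord, ties.method = "first")
  cls <- colnames(post_ord)[win]
  dplyr::bind_cols(tibble(.class = cls, .code = class_code(cls)),
                   as_tibble(post))
}

#' Serialize / restore a fitted classifier
#'
#' Writes the model (class means, pooled covariance, priors, counts,
#' feature schema, configuration) as JSON; `read_ldc()` restores a model
#' whose predictions are identical to the original's.
#'
#' @param model A `plaque_ldc`.
#' @param path File path for the JSON model.
#' @return `path` (write) or the restored `plaque_ldc` (read), invisibly
#'   for the writer.
#' @export
write_ldc <- function(model, path) {
  stopifnot(inherits(model, "plaque_ldc"))
  payload <- list(
    classes = model$classes,
    feature_names = model$feature_names,
    means = model$means,
    covariance = model$covariance,
    priors = as.list(model$priors),
    counts = as.list(model$counts),
    n_train = model$n_train,
    config = unclass(model$config),
    standardize = model$standardize)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ldc
#' @export
read_ldc <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(classifier_config, p$config)
  means <- matrix(as.numeric(p$means), nrow = length(p$classes),
                  dimnames = list(p$classes, p$feature_names))
  covariance <- matrix(as.numeric(p$covariance),
                       nrow = length(p$feature_names),
                       dimnames = list(p$feature_names, p$feature_names))
  model <- structure(list(
    classes = p$classes, means = means, covariance = covariance,
    chol = chol(covariance),
    priors = unlist(p$priors), counts = unlist(p$counts),
    feature_names = p$feature_names, config = cfg,
    n_train = p$n_train), class = "plaque_ldc")
  if (length(p$standardize) > 0) {
    model$standardize <- lapply(p$standardize, unlist)
  }
  model
}
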