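#' Known-motif rule model
#'
#' Rule-based predictor: a site is called cleaved when it matches any of a
#' fixed set of positional patterns over its P-side residues. The default
#' set encodes the canonical prohormone convertase specificity reported
#' across species: any dibasic pair (K/R at P2 and K/R at P1), or R at
#' both P4 and P1. Monobasic (single-R) sites match no default pattern.
#'
#' @param motif_set Named list of patterns; each pattern is a named
#'   character vector mapping P-side positions (`"P1"`, `"P2"`, `"P4"`,
#'   ... up to the window's `upstream`) to a string of allowed residues.
#' @return An object of class `known_motif_model`.
#' @examples
#' m <- known_motif_model()  # dibasic + RxxR rules
#' @export
known_motif_model <- function(motif_set = list(
    dibasic = c(P1 = "KR", P2 = "KR"),
    RxxR = c(P1 = "R", P4 = "R"))) {
  stopifnot(is.list(motif_set), length(motif_set) > 0L)
  for (pat in motif_set) {
    offs <- as.integer(sub("^P", "", names(pat)))
    if (any(is.na(offs)) || any(offs < 1L)) {
      stop("pattern positions must be named P1, P2, ...", call. = FALSE)
    }
  }
  structure(list(kind = "known_motif", motif_set = motif_set,
                 threshold = 0.5),
            class = c("known_motif_model", "cleavage_model"))
}

# P-side offsets: P_k is window index upstream - k + 1.
match_motif_set <- function(windows, motif_set, upstream) {
  chars <- window_chars(windows)
  hit <- rep(FALSE, length(windows))
  for (pat in motif_set) {
    offs <- as.integer(sub("^P", "", names(pat)))
    if (any(offs > upstream)) {
      stop("pattern references P", max(offs),
           " outside the configured window (upstream = ", upstream, ")",
           call. = FALSE)
    }
    ok <- rep(TRUE, length(windows))
    for (i in seq_along(offs)) {
      allowed <- strsplit(pat[[i]], "")[[1]]
      ok <- ok & chars[, upstream - offs[i] + 1L] %in% allowed
    }
    hit <- hit | ok
  }
  hit
}

#' Predict cleavage with the known-motif rule
#'
#' @param sites Candidate-site data frame from [enumerate_sites()].
#' @param model A [known_motif_model()] (default rule set if omitted).
#' @param upstream P-side window length used when the site table carries
#'   no `site_config` attribute.
#' @return Numeric vector of scores in \{0, 1\}, one per site.
#' @export
known_motif_predict <- function(sites, model = known_motif_model(),
                                upstream = NULL) {
  cfg <- attr(sites, "site_config")
  if (is.null(upstream)) {
    upstream <- if (is.null(cfg)) 9L else cfg$upstream
  }
  as.numeric(match_motif_set(sites$window, model$motif_set, upstream))
}

sigmoid <- function(x) plogis(x)

# Numerically stable sum(log(1 + exp(eta)) - y * eta).
nll_bernoulli <- function(eta, y) {
  sum(pmax(eta, 0) + log1p(exp(-abs(eta))) - y * eta)
}

new_trained_model <- function(kind, scheme, config, parameters, table,
                              train_meta, threshold = 0.5) {
  structure(list(kind = kind, scheme = scheme, site_config = config,
                 parameters = parameters, property_table = table,
                 threshold = threshold, train_meta = train_meta),
            class = c(paste0(kind, "_model"), "trained_model",
                      "cleavage_model"))
}

#' @export
print.trained_model <- function(x, ...) {
  cat("<trained cleavage model> kind=", x$kind, " scheme=", x$scheme,
      " window=", x$site_config$upstream, "+", x$site_config$downstream,
      " threshold=", x$threshold, "\n", sep = "")
  cat("  trained on ", x$train_meta$n_sites, " sites (",
      x$train_meta$n_cleaved, " cleaved), seed=", x$train_meta$seed,
      ", l2=", x$train_meta$l2, ", converged=", x$train_meta$converged,
      "\n", sep = "")
  invisible(x)
}

check_trainable <- function(sites) {
  stopifnot(is.data.frame(sites), all(c("window", "cleaved") %in% names(sites)))
  if (nrow(sites) < 2L || length(unique(sites$cleaved)) < 2L) {
    stop("training requires both cleaved and non-cleaved sites",
         call. = FALSE)
  }
}

site_table_config <- function(sites) {
  cfg <- attr(sites, "site_config")
  if (is.null(cfg)) {
    stop("site table carries no site_config attribute; ",
         "build it with enumerate_sites()", call. = FALSE)
  }
  cfg
}

#' Train an L2-regularised logistic cleavage model
#'
#' Maximum-likelihood logistic regression on encoded site windows, with a
#' ridge penalty `n * l2/2 * ||w||^2` on the weights (intercept
#' unpenalised) so the optimum is finite and unique even when the
#' encoding separates the classes. The penalty is scaled per observation,
#' which makes the fit exactly invariant to duplicating the training set.
#' The fit is a deterministic quasi-Newton (BFGS) solve from a zero
#' start; identical inputs and seed give bit-identical parameters.
#'
#' @param sites Labelled candidate-site data frame (both classes present).
#' @param scheme `"AA"` or `"AA_PROP"` (see [encode_windows()]).
#' @param l2 Non-negative ridge strength (default `1e-4`).
#' @param seed Integer seed recorded in the artifact (the convex fit does
#'   not consume randomness, but the contract is uniform across models).
#' @param table Optional `property_table` for `"AA_PROP"`.
#' @param maxit Iteration cap for the optimiser.
#' @return A `trained_model` with a weight vector and intercept.
#' @export
train_logistic <- function(sites, scheme = c("AA", "AA_PROP"), l2 = 1e-4,
                           seed = 1L, table = NULL, maxit = 1000L) {
  scheme <- match.arg(scheme)
  check_trainable(sites)
  stopifnot(l2 >= 0)
  if (scheme == "AA_PROP" && is.null(table)) table <- load_property_table()
  X <- encode_sites(sites, scheme = scheme, table = table)
  if (!all(is.finite(X))) stop("non-finite feature values", call. = FALSE)
  y <- as.numeric(sites$cleaved)
  d <- ncol(X)
  lam <- l2 * nrow(X)                     # per-observation penalty scaling
  fn <- function(par) {
    eta <- drop(X %*% par[-1L]) + par[1L]
    nll_bernoulli(eta, y) + lam / 2 * sum(par[-1L]^2)
  }
  gr <- function(par) {
    eta <- drop(X %*% par[-1L]) + par[1L]
    r <- sigmoid(eta) - y
    c(sum(r), drop(crossprod(X, r)) + lam * par[-1L])
  }
  fit <- optim(rep(0, d + 1L), fn, gr, method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-10))
  meta <- list(seed = as.integer(seed), l2 = l2,
               converged = fit$convergence == 0L,
               final_nll = fit$value, n_sites = nrow(sites),
               n_cleaved = sum(y))
  new_trained_model("logistic", scheme, site_table_config(sites),
                    list(intercept = fit$par[1L],
                         weights = setNames(fit$par[-1L], colnames(X))),
                    table, meta)
}

ann_unpack <- function(par, d, h) {
  i <- 0L
  W1 <- matrix(par[i + seq_len(d * h)], d, h); i <- i + d * h
  b1 <- par[i + seq_len(h)]; i <- i + h
  w2 <- par[i + seq_len(h)]; i <- i + h
  b2 <- par[i + 1L]
  list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
}

ann_forward <- function(X, p) {
  Z <- sigmoid(sweep(X %*% p$W1, 2L, p$b1, "+"))
  eta <- drop(Z %*% p$w2) + p$b2
  list(Z = Z, eta = eta, prob = sigmoid(eta))
}

#' Train a one-hidden-layer neural-network cleavage model
#'
#' Feed-forward network with one hidden layer of logistic units and a
#' sigmoid output, trained by full-batch quasi-Newton (BFGS) minimisation
#' of the penalised cross-entropy (per-observation ridge `n * l2/2` on
#' all weights, biases unpenalised) from a seeded uniform initialisation. Unlike the logistic
#' model, hidden units let the network express interactions between
#' window positions (e.g. conjunctions of P2 and P4 residues).
#'
#' @inheritParams train_logistic
#' @param hidden Number of hidden units (default 5).
#' @param max_epochs Optimiser iteration cap (default 5000).
#' @param tol Relative convergence tolerance (default `1e-6`).
#' @return A `trained_model` with layer weight matrices and biases.
#'   Non-convergence within `max_epochs` is recorded in `train_meta` with
#'   a warning; the model is still returned.
#' @export
train_ann <- function(sites, scheme = c("AA", "AA_PROP"), hidden = 5L,
                      l2 = 1e-4, seed = 1L, max_epochs = 5000L,
                      tol = 1e-6, table = NULL) {
  scheme <- match.arg(scheme)
  check_trainable(sites)
  stopifnot(l2 >= 0, hidden >= 1L)
  if (scheme == "AA_PROP" && is.null(table)) table <- load_property_table()
  X <- encode_sites(sites, scheme = scheme, table = table)
  if (!all(is.finite(X))) stop("non-finite feature values", call. = FALSE)
  y <- as.numeric(sites$cleaved)
  d <- ncol(X); h <- as.integer(hidden)
  npar <- d * h + h + h + 1L
  penal_mask <- c(rep(1, d * h), rep(0, h), rep(1, h), 0)
  lam <- l2 * nrow(X)                     # per-observation penalty scaling
  fn <- function(par) {
    p <- ann_unpack(par, d, h)
    f <- ann_forward(X, p)
    nll_bernoulli(f$eta, y) + lam / 2 * sum((par * penal_mask)^2)
  }
  gr <- function(par) {
    p <- ann_unpack(par, d, h)
    f <- ann_forward(X, p)
    r <- f$prob - y                       # d NLL / d eta_out
    g_w2 <- drop(crossprod(f$Z, r))
    g_b2 <- sum(r)
    delta1 <- (r %o% p$w2) * f$Z * (1 - f$Z)
    g_W1 <- crossprod(X, delta1)
    g_b1 <- colSums(delta1)
    c(as.vector(g_W1), g_b1, g_w2, g_b2) + lam * par * penal_mask
  }
  set.seed(as.integer(seed))
  init <- runif(npar, -0.5, 0.5)
  fit <- optim(init, fn, gr, method = "BFGS",
               control = list(maxit = as.integer(max_epochs), reltol = tol))
  converged <- fit$convergence == 0L
  if (!converged) {
    warning("ANN training did not converge within ", max_epochs,
            " iterations (recorded in train_meta)", call. = FALSE)
  }
  meta <- list(seed = as.integer(seed), l2 = l2, hidden = h,
               converged = converged, final_nll = fit$value,
               epochs = as.integer(max_epochs), n_sites = nrow(sites),
               n_cleaved = sum(y))
  new_trained_model("ann", scheme, site_table_config(sites),
                    ann_unpack(fit$par, d, h), table, meta)
}

#' Score candidate sites with a cleavage model
#'
#' Returns, in site order, the probability of cleavage (logistic/ANN) or
#' the binary rule output in \{0, 1\} (known-motif). Stateless: scoring a
#' split of the table equals the split of the scores.
#'
#' @param model A `cleavage_model` (rule-based or trained).
#' @param sites Candidate-site data frame; windows must match the model's
#'   configured window length.
#' @return Numeric scores in `[0, 1]`.
#' @export
predict_scores <- function(model, sites) {
  stopifnot(inherits(model, "cleavage_model"), is.data.frame(sites))
  if (nrow(sites) == 0L) return(numeric(0))
  if (model$kind == "known_motif") {
    return(known_motif_predict(sites, model))
  }
  want <- model$site_config$upstream + model$site_config$downstream
  have <- unique(nchar(sites$window))
  if (length(have) != 1L || have != want) {
    stop("window/scheme mismatch: model expects windows of length ", want,
         " (scheme ", model$scheme, "), sites have length ",
         paste(have, collapse = "/"), call. = FALSE)
  }
  X <- encode_sites(sites, scheme = model$scheme,
                    table = model$property_table)
  if (model$kind == "logistic") {
    sigmoid(drop(X %*% model$parameters$weights) +
              model$parameters$intercept)
  } else {
    ann_forward(X, model$parameters)$prob
  }
}

#' Threshold scores into cleavage calls
#'
#' A site is called cleaved when its score is greater than or equal to
#' the threshold.
#'
#' @param scores Numeric scores in `[0, 1]`.
#' @param threshold Decision cutoff, strictly inside `(0, 1)`.
#' @return Logical vector (`TRUE` = cleaved).
#' @export
apply_threshold <- function(scores, threshold = 0.5) {
  stopifnot(is.numeric(scores))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly between 0 and 1", call. = FALSE)
  }
  if (any(scores < 0 | scores > 1, na.rm = TRUE)) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  scores >= threshold
}

MODEL_SCHEMA_VERSION <- 1L

#' Serialise / deserialise a cleavage model
#'
#' Models are stored as a single self-describing JSON artifact: schema
#' version, model kind, encoding scheme, window configuration, the
#' standardised property table and its hash (for `AA_PROP`), all
#' parameters, the decision threshold, and training metadata.
#'
#' @param model A `cleavage_model`.
#' @param path Output (or input) file path.
#' @return `write_model()`: invisibly, `path`. `read_model()`: the model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "cleavage_model"))
  obj <- list(schema_version = MODEL_SCHEMA_VERSION,
              package_version = as.character(packageVersion("procleave")),
              kind = model$kind)
  if (model$kind == "known_motif") {
    obj$motif_set <- lapply(model$motif_set, as.list)
    obj$threshold <- model$threshold
  } else {
    tab <- model$property_table
    obj$scheme <- model$scheme
    obj$site_config <- unclass(model$site_config)
    obj$threshold <- model$threshold
    obj$train_meta <- model$train_meta
    if (!is.null(tab)) {
      obj$property_table <- list(residues = rownames(tab),
                                 scales = colnames(tab),
                                 values = unclass(tab),
                                 hash = property_table_hash(tab))
    }
    if (model$kind == "logistic") {
      obj$parameters <- list(intercept = model$parameters$intercept,
                             weights = as.list(model$parameters$weights))
    } else {
      obj$parameters <- list(W1 = model$parameters$W1,
                             b1 = model$parameters$b1,
                             w2 = model$parameters$w2,
                             b2 = model$parameters$b2)
    }
  }
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

property_table_hash <- function(tab) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(format(tab, digits = 15), collapse = ","), f)
  unname(tools::md5sum(f))
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (is.null(obj$schema_version) ||
      obj$schema_version > MODEL_SCHEMA_VERSION) {
    stop("unsupported model artifact schema", call. = FALSE)
  }
  if (obj$kind == "known_motif") {
    return(known_motif_model(lapply(obj$motif_set, unlist)))
  }
  cfg <- site_config(obj$site_config$upstream, obj$site_config$downstream,
                     obj$site_config$exclude_signal, obj$site_config$pad_char)
  tab <- NULL
  if (!is.null(obj$property_table)) {
    tab <- obj$property_table$values
    rownames(tab) <- obj$property_table$residues
    colnames(tab) <- obj$property_table$scales
    class(tab) <- c("property_table", class(tab))
  }
  if (obj$kind == "logistic") {
    params <- list(intercept = obj$parameters$intercept,
                   weights = unlist(obj$parameters$weights))
  } else {
    params <- list(W1 = obj$parameters$W1, b1 = obj$parameters$b1,
                   w2 = obj$parameters$w2, b2 = obj$parameters$b2)
  }
  new_trained_model(obj$kind, obj$scheme, cfg, params, tab,
                    obj$train_meta, obj$threshold)
}
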