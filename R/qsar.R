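# QSAR model selection and validation. A chromosome is a descriptor
# subset; fitness is training-set R-squared with a parsimony penalty; the
# best subset's ordinary-least-squares model is validated on a held-out
# split and by leave-one-out cross-validation (subset held fixed across
# folds). The frozen published two-descriptor binding-energy model is
# exposed separately and is never refit.

# Frozen constants of the published binding-energy equation:
# S = -1.26777 - 0.01161 * vsurf_S + 0.00007 * wienerPath  (kcal/mol)
.EQ1_INTERCEPT <- -1.26777
.EQ1_COEF <- c(vsurf_S = -0.01161, wienerPath = 0.00007)

#' Construct a QSAR model object
#'
#' @param intercept model intercept, kcal/mol.
#' @param coefficients named numeric vector of descriptor coefficients.
#' @param stats list of fit statistics (`r2`, `q2`, `n_train`, `n_test`,
#'   `train_r2`, `test_r2` where defined).
#' @param provenance free-text origin tag.
#' @return object of class `qsar_model`.
#' @export
qsar_model <- function(intercept, coefficients, stats = list(),
                       provenance = "fitted") {
  stopifnot(is.numeric(intercept), length(intercept) == 1,
            !is.null(names(coefficients)))
  structure(list(intercept = as.numeric(intercept),
                 coefficients = coefficients, stats = stats,
                 provenance = provenance),
            class = "qsar_model")
}

#' @export
print.qsar_model <- function(x, ...) {
  terms <- paste(sprintf("%+.6g*%s", x$coefficients, names(x$coefficients)),
                 collapse = " ")
  cat(sprintf("<qsar_model (%s): S = %.6g %s>\n", x$provenance,
              x$intercept, terms))
  if (length(x$stats) > 0)
    cat("  stats:", paste(names(x$stats), signif(unlist(x$stats), 4),
                          sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' The frozen published two-descriptor model
#'
#' Intercept -1.26777 kcal/mol, -0.01161 per Angstrom^2 of
#' interaction-field surface area, +0.00007 per Wiener-path unit; reported
#' fit R^2 0.9359 and LOO q^2 0.9003. The constants are frozen and never
#' refit.
#'
#' @return a `qsar_model`.
#' @export
published_model <- function() {
  qsar_model(.EQ1_INTERCEPT, .EQ1_COEF,
             stats = list(r2 = 0.9359, q2 = 0.9003),
             provenance = "published")
}

#' Predict with the frozen published model
#'
#' @param vsurf_S interaction-field surface area, Angstrom^2.
#' @param wienerPath Wiener path number.
#' @return predicted binding-energy score S, kcal/mol (vectorised).
#' @export
published_model_predict <- function(vsurf_S, wienerPath) {
  stopifnot(all(is.finite(vsurf_S)), all(is.finite(wienerPath)))
  .EQ1_INTERCEPT + .EQ1_COEF[["vsurf_S"]] * vsurf_S +
    .EQ1_COEF[["wienerPath"]] * wienerPath
}

#' Random train/test split specification
#' @param seed integer seed.
#' @param train_fraction proportion of compounds in the training set.
#' @return object of class `split_spec`.
#' @export
split_spec <- function(seed = 1L, train_fraction = 0.8) {
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("train_fraction must be in (0, 1)")
  structure(list(seed = as.integer(seed),
                 train_fraction = train_fraction), class = "split_spec")
}

#' Split compound ids into training and test sets
#'
#' Training size is `round(train_fraction * n)` (490 compounds at 0.8
#' give 392/98); the split is deterministic per seed.
#'
#' @param ids unique compound identifiers.
#' @param spec a [split_spec()].
#' @return list with `train` and `test` id vectors (disjoint, union = ids).
#' @export
split_train_test <- function(ids, spec = split_spec()) {
  if (anyDuplicated(ids)) stop("compound ids must be unique")
  n <- length(ids)
  if (n < 2) stop("need at least 2 compounds to split")
  n_train <- round(spec$train_fraction * n)
  n_train <- min(max(n_train, 1L), n - 1L)
  train <- with_seed(spec$seed, sort(sample(ids, n_train)))
  list(train = train, test = setdiff(ids, train))
}

# design matrix for a descriptor subset (with intercept column)
.design <- function(table, subset) {
  M <- descriptor_matrix(table)
  miss <- setdiff(subset, colnames(M))
  if (length(miss) > 0)
    stop("descriptor(s) not in table: ", paste(miss, collapse = ", "))
  cbind(`(Intercept)` = 1, M[, subset, drop = FALSE])
}

#' Fit an ordinary-least-squares QSAR model on a descriptor subset
#'
#' @param table a `descriptor_table`.
#' @param subset character vector of descriptor names to use.
#' @param response named numeric response (default the table's own).
#' @return a `qsar_model` with the training R^2 in `stats$r2`. A constant
#'   response yields the degenerate convention: all coefficients zero and
#'   R^2 = 0. A rank-deficient design is an error naming the collinear
#'   columns.
#' @export
fit_ols <- function(table, subset, response = response_of(table)) {
  if (is.null(response)) stop("no response available")
  y <- as.numeric(response[table$compound_id])
  if (any(is.na(y))) stop("response missing for some compounds")
  X <- .design(table, subset)
  if (nrow(X) < ncol(X) + 1)
    stop("need n >= k+2 observations (n=", nrow(X), ", k=", ncol(X) - 1, ")")
  if (stats::var(y) == 0) {
    return(qsar_model(y[1],
                      stats::setNames(rep(0, length(subset)), subset),
                      stats = list(r2 = 0, n_train = nrow(X))))
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qr_x, y)
  resid <- y - X %*% beta
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  qsar_model(beta[1], beta[-1], stats = list(r2 = r2, n_train = nrow(X)))
}

#' Predict binding-energy scores from a QSAR model
#' @param model a `qsar_model`.
#' @param table a `descriptor_table` containing the model's descriptors.
#' @return named numeric vector of predictions.
#' @export
predict_qsar <- function(model, table) {
  X <- .design(table, names(model$coefficients))
  stats::setNames(as.numeric(X %*% c(model$intercept, model$coefficients)),
                  table$compound_id)
}

#' Coefficient of determination of a model on a table
#'
#' `1 - SS_res/SS_tot`, with the reference mean taken from the evaluation
#' set itself; can be negative for a bad model, never above 1.
#'
#' @param model a `qsar_model`.
#' @param table a `descriptor_table`.
#' @param response named response (default the table's own).
#' @return numeric R^2.
#' @export
r_squared <- function(model, table, response = response_of(table)) {
  y <- as.numeric(response[table$compound_id])
  if (length(y) < 2) stop("need at least 2 compounds to evaluate R^2")
  if (stats::var(y) == 0) stop("zero-variance response")
  yhat <- predict_qsar(model, table)
  1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
}

#' Leave-one-out cross-validated R^2 (q^2)
#'
#' The descriptor subset is held fixed; only the OLS coefficients are
#' refit with each compound left out. Computed through the hat-matrix
#' identity for leave-one-out residuals (e_i / (1 - h_ii)), which equals
#' the explicit n-refit loop exactly.
#'
#' @param table a `descriptor_table`.
#' @param subset descriptor names of the model.
#' @param response named response (default the table's own).
#' @return q^2 (at most 1; can be negative).
#' @export
loo_q2 <- function(table, subset, response = response_of(table)) {
  y <- as.numeric(response[table$compound_id])
  X <- .design(table, subset)
  if (nrow(X) < ncol(X) + 2)
    stop("need n >= k+3 observations for LOO")
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) stop("rank-deficient design")
  beta <- qr.coef(qr_x, y)
  resid <- as.numeric(y - X %*% beta)
  h <- rowSums(qr.Q(qr_x)^2)
  press <- sum((resid / (1 - h))^2)
  1 - press / sum((y - mean(y))^2)
}

#' Genetic-algorithm configuration
#'
#' @param pop_size chromosomes per generation.
#' @param generations number of generations.
#' @param crossover_rate one-point crossover probability.
#' @param mutation_rate per-bit flip probability.
#' @param elitism chromosomes copied unchanged to the next generation.
#' @param max_descriptors largest allowed subset.
#' @param parsimony fitness penalty per selected descriptor.
#' @param seed integer seed.
#' @return object of class `ga_config`.
#' @export
ga_config <- function(pop_size = 100L, generations = 200L,
                      crossover_rate = 0.8, mutation_rate = 0.01,
                      elitism = 1L, max_descriptors = 4L,
                      parsimony = 0.01, seed = 1L) {
  stopifnot(max_descriptors >= 1)
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 elitism = as.integer(elitism),
                 max_descriptors = as.integer(max_descriptors),
                 parsimony = parsimony, seed = as.integer(seed)),
            class = "ga_config")
}

# training-set R^2 of a subset (NA on degenerate designs), fast path
.subset_r2 <- function(Xall, y, sel) {
  X <- Xall[, c(1L, which(sel) + 1L), drop = FALSE]
  fit <- tryCatch(stats::.lm.fit(X, y), error = function(e) NULL)
  if (is.null(fit) || any(is.na(fit$coefficients))) return(NA_real_)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' Genetic-algorithm descriptor selection
#'
#' Evolves descriptor subsets (bit chromosomes over the table's columns)
#' by tournament selection, one-point crossover and per-bit mutation, with
#' elitism; fitness is the training-set R^2 minus a parsimony penalty per
#' descriptor. Returns the best subset's OLS model fitted on the training
#' split, with training, test, whole-set and leave-one-out statistics.
#' Fully reproducible per seed.
#'
#' @param table a `descriptor_table`.
#' @param ga a [ga_config()].
#' @param split a [split_spec()].
#' @param response named response (default the table's own).
#' @return a `qsar_model`; the fitness trace is in attribute
#'   `"fitness_trace"` (best fitness per generation, non-decreasing).
#' @export
ga_evolve <- function(table, ga = ga_config(), split = split_spec(),
                      response = response_of(table)) {
  if (is.null(response)) stop("no response available")
  M <- descriptor_matrix(table)
  keep <- apply(M, 2, function(col) stats::var(col) > 0)
  if (!any(keep)) stop("no usable descriptor column (all constant)")
  pool <- colnames(M)[keep]
  p <- length(pool)
  kmax <- min(ga$max_descriptors, p)
  parts <- split_train_test(table$compound_id, split)
  tri <- match(parts$train, table$compound_id)
  ytr <- as.numeric(response[parts$train])
  Xall <- cbind(1, M[tri, pool, drop = FALSE])

  run <- with_seed(ga$seed, {
    repair <- function(sel) {
      on <- which(sel)
      if (length(on) > kmax) sel[sample(on, length(on) - kmax)] <- FALSE
      if (!any(sel)) sel[sample.int(p, 1L)] <- TRUE
      sel
    }
    fitness_of <- function(sel) {
      r2 <- .subset_r2(Xall, ytr, sel)
      if (is.na(r2)) -Inf else r2 - ga$parsimony * sum(sel)
    }
    popn <- lapply(seq_len(ga$pop_size), function(q) {
      sel <- rep(FALSE, p)
      sel[sample.int(p, sample.int(kmax, 1L))] <- TRUE
      sel
    })
    fits <- vapply(popn, fitness_of, 1.0)
    trace <- numeric(ga$generations)
    for (gen in seq_len(ga$generations)) {
      ord <- order(fits, decreasing = TRUE)
      nextgen <- popn[ord[seq_len(ga$elitism)]]
      while (length(nextgen) < ga$pop_size) {
        pick <- function() {
          c2 <- sample.int(ga$pop_size, 2L)
          if (fits[c2[1]] >= fits[c2[2]]) popn[[c2[1]]] else popn[[c2[2]]]
        }
        pa <- pick(); pb <- pick()
        if (runif(1) < ga$crossover_rate && p > 1) {
          cut <- sample.int(p - 1L, 1L)
          child <- c(pa[seq_len(cut)], pb[(cut + 1L):p])
        } else child <- pa
        flip <- runif(p) < ga$mutation_rate
        child <- xor(child, flip)
        nextgen[[length(nextgen) + 1L]] <- repair(child)
      }
      popn <- nextgen
      fits <- vapply(popn, fitness_of, 1.0)
      trace[gen] <- max(fits)
    }
    best <- popn[[which.max(fits)]]
    # deterministic backward-elimination polish: per-bit mutation keeps
    # re-adding hitchhiker columns, so drop any descriptor whose removal
    # improves the penalised fitness until the subset is locally minimal
    repeat {
      fbest <- fitness_of(best)
      on <- which(best)
      if (length(on) <= 1L) break
      drop_fit <- vapply(on, function(bit) {
        cand <- best; cand[bit] <- FALSE
        fitness_of(cand)
      }, 1.0)
      if (max(drop_fit) <= fbest) break
      best[on[which.max(drop_fit)]] <- FALSE
    }
    list(subset = pool[best], trace = cummax(trace))
  })

  train_tab <- table[tri, , drop = FALSE]
  class(train_tab) <- class(table)
  model <- fit_ols(train_tab, run$subset, response)
  tei <- match(parts$test, table$compound_id)
  test_tab <- table[tei, , drop = FALSE]
  class(test_tab) <- class(table)
  model$stats <- list(
    r2 = r_squared(model, table, response),
    train_r2 = model$stats$r2,
    test_r2 = if (length(tei) >= 2) r_squared(model, test_tab, response)
              else NA_real_,
    q2 = loo_q2(table, run$subset, response),
    n_train = length(parts$train), n_test = length(parts$test))
  model$provenance <- "ga_evolve"
  attr(model, "fitness_trace") <- run$trace
  attr(model, "split") <- parts
  model
}

# --- model JSON io ---------------------------------------------------------

#' Write a QSAR model to JSON
#'
#' Layout: `{intercept, coefficients: {name: value}, stats, provenance}`,
#' full float precision; round-trips through [read_qsar_model()].
#'
#' @param model a `qsar_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qsar_model <- function(model, path) {
  jsonlite::write_json(
    list(intercept = model$intercept,
         coefficients = as.list(model$coefficients),
         stats = model$stats, provenance = model$provenance),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a QSAR model from JSON
#' @param path JSON path written by [write_qsar_model()].
#' @return a `qsar_model`.
#' @export
read_qsar_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$intercept) || is.null(j$coefficients))
    stop("model JSON lacks intercept/coefficients")
  qsar_model(j$intercept, unlist(j$coefficients),
             stats = as.list(j$stats), provenance = j$provenance)
}
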