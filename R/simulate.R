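# Mock-community and sequencing-depth simulation, plus the binomial
# detection-probability model.
#
# The amplification-efficiency model (e = e_max * delta3^m3 * delta5^m5)
# and the multinomial read-sampling abstraction are this package's own
# constructions: they encode the qualitative observations that 3'-zone
# primer mismatches depress per-cycle efficiency far more than remainder
# mismatches, and that finite sequencing depth makes rare templates easy
# to miss. All their parameters live in `efficiency_params()`.

#' Default efficiency-model parameters
#'
#' @param e_max maximal per-cycle amplification efficiency (default 0.95).
#' @param delta3 multiplicative efficiency penalty per 3'-zone mismatch
#'   (default 0.3).
#' @param delta5 penalty per remainder mismatch (default 0.8).
#' @return named list.
#' @export
efficiency_params <- function(e_max = 0.95, delta3 = 0.3, delta5 = 0.8) {
  stopifnot(e_max > 0, e_max <= 1, delta3 > 0, delta3 <= 1,
            delta5 > 0, delta5 <= 1)
  list(e_max = e_max, delta3 = delta3, delta5 = delta5)
}

#' Map a zoned mismatch profile to an amplification efficiency
#'
#' `e = e_max * delta3^m3 * delta5^m5`: strictly decreasing in both
#' counts, with a 3'-zone mismatch at least as damaging as a remainder
#' mismatch whenever `delta3 <= delta5`.
#'
#' @param m3,m5 nonnegative mismatch counts (vectorized).
#' @param params list from [efficiency_params()].
#' @return efficiencies in `(0, e_max]`.
#' @export
mismatch_to_efficiency <- function(m3, m5, params = efficiency_params()) {
  if (any(m3 < 0) || any(m5 < 0)) {
    stop("mismatch counts must be nonnegative", call. = FALSE)
  }
  params$e_max * params$delta3^m3 * params$delta5^m5
}

#' Enumerate mock-community library specifications
#'
#' Cartesian product of extract sets, balance levels, and replicates,
#' enumerated deterministically with stable library identifiers.
#'
#' @param n_sets number of distinct DNA-extract sets (default 3).
#' @param balance_levels subset of `c("balanced", "unbalanced")` (default
#'   both).
#' @param replicates replicates per set x balance level (default 3).
#' @param members members per set (default 85).
#' @return data.frame `library_id`, `set`, `balance`, `replicate`,
#'   `members`; `nrow = n_sets * length(balance_levels) * replicates`.
#' @examples
#' nrow(build_mock_design(3, c("balanced", "unbalanced"), 3))  # 18
#' @export
build_mock_design <- function(n_sets = 3L,
                              balance_levels = c("balanced", "unbalanced"),
                              replicates = 3L, members = 85L) {
  stopifnot(n_sets >= 1L, replicates >= 1L, members >= 1L,
            length(balance_levels) >= 1L,
            all(balance_levels %in% c("balanced", "unbalanced")))
  grid <- expand.grid(replicate = seq_len(replicates),
                      balance = balance_levels, set = seq_len(n_sets),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("set", "balance", "replicate")]
  grid$library_id <- sprintf("set%d_%s_rep%d", grid$set, grid$balance,
                             grid$replicate)
  grid$members <- members
  grid[, c("library_id", "set", "balance", "replicate", "members")]
}

#' Balance member concentrations by capping
#'
#' Extracts above the cap are diluted to the cap; everything below is
#' left unaltered (low concentrations cannot be measured precisely enough
#' to adjust upward). Order is preserved. Units are whatever the
#' concentrations were configured in; only relative concentrations matter
#' downstream.
#'
#' @param members data.frame with a `concentration` column, or a numeric
#'   vector.
#' @param cap concentration cap (default 5.0).
#' @return same shape as `members`, capped.
#' @export
balance_concentrations <- function(members, cap = 5.0) {
  stopifnot(cap > 0)
  if (is.data.frame(members)) {
    members$concentration <- pmin(members$concentration, cap)
    members
  } else {
    pmin(members, cap)
  }
}

#' Deterministic competitive-amplification proportions
#'
#' Template weight after `cycles` cycles is
#' `concentration * (1 + efficiency)^cycles`, normalized over members.
#' This stage is deterministic; stochasticity enters only at read
#' sampling.
#'
#' @param members data.frame with `concentration` and `efficiency`
#'   columns.
#' @param cycles nonnegative cycle count (default 35).
#' @return numeric vector of proportions summing to 1.
#' @export
simulate_amplification <- function(members, cycles = 35L) {
  stopifnot(cycles >= 0, all(members$concentration >= 0),
            all(members$efficiency >= 0), all(members$efficiency <= 1))
  w <- members$concentration * (1 + members$efficiency)^cycles
  if (all(w == 0)) stop("all amplification weights are zero", call. = FALSE)
  w / sum(w)
}

#' Sample reads for one library
#'
#' Multinomial draw of `depth` reads over member proportions,
#' reproducible under `seed`.
#'
#' @param proportions numeric vector summing to 1 (tolerance 1e-9).
#' @param depth total read count (>= 0).
#' @param seed RNG seed for this draw.
#' @return list of class `sequencing_run`: `counts` (integer vector, sums
#'   to `depth`), `depth`, `seed`.
#' @export
sample_reads <- function(proportions, depth, seed) {
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("proportions do not sum to 1", call. = FALSE)
  }
  stopifnot(depth >= 0)
  counts <- if (depth == 0) {
    rep(0L, length(proportions))
  } else {
    as.integer(.with_seed(seed, stats::rmultinom(1L, depth, proportions)))
  }
  structure(list(counts = counts, depth = as.integer(depth),
                 seed = as.integer(seed)),
            class = "sequencing_run")
}

#' Detection calls from read counts
#'
#' @param run a `sequencing_run` (or a bare count vector).
#' @param r_min minimum read count for a detection (default 1).
#' @return logical vector.
#' @export
detect <- function(run, r_min = 1L) {
  stopifnot(r_min >= 1L)
  counts <- if (inherits(run, "sequencing_run")) run$counts else run
  counts >= r_min
}

#' Simulate a full detection experiment
#'
#' Generates `n_libraries` mock communities and sequences each once:
#' member concentrations are drawn lognormally, optionally
#' balance-capped, zoned mismatch profiles are assigned by `profile_probs`
#' and mapped to per-cycle efficiencies, competitive amplification sets
#' read proportions, and a multinomial draw at a log-uniform depth yields
#' counts and detections. Every library derives its own seed from
#' (`library_id`, `seed`) so the experiment is reproducible end to end.
#'
#' @param n_libraries number of libraries (default 1000).
#' @param members community members per library (default 85).
#' @param conc_meanlog,conc_sdlog lognormal concentration parameters
#'   (defaults 0.5 and 1.5, giving extract concentrations spanning about
#'   three orders of magnitude).
#' @param balance `"balanced"` (cap at `cap`), `"unbalanced"`, or a
#'   vector recycled over libraries.
#' @param cap balancing cap (default 5.0).
#' @param depth_range depths drawn log-uniformly from this interval
#'   (default `c(1e3, 1e5)`).
#' @param cycles PCR cycles (default 35).
#' @param profile_probs named numeric vector of probabilities over
#'   `"m3,m5"` profile strings (default: every member a perfect match,
#'   `c("0,0" = 1)`).
#' @param params efficiency parameters, see [efficiency_params()].
#' @param r_min detection threshold (default 1).
#' @param seed root seed (required).
#' @return tidy data.frame: `library_id`, `taxon_id`, `class`,
#'   `concentration`, `rel_conc`, `m3`, `m5`, `efficiency`, `proportion`,
#'   `count`, `detected`, `depth`, `seed`.
#' @export
simulate_experiment <- function(n_libraries = 1000L, members = 85L,
                                conc_meanlog = 0.5, conc_sdlog = 1.5,
                                balance = "unbalanced", cap = 5.0,
                                depth_range = c(1e3, 1e5), cycles = 35L,
                                profile_probs = c("0,0" = 1),
                                params = efficiency_params(),
                                r_min = 1L, seed) {
  stopifnot(!missing(seed), n_libraries >= 1L, members >= 2L,
            length(depth_range) == 2L, depth_range[1] <= depth_range[2],
            abs(sum(profile_probs) - 1) < 1e-9)
  balance <- rep_len(balance, n_libraries)
  prof <- do.call(rbind, lapply(strsplit(names(profile_probs), ","),
                                as.integer))
  classes <- paste0("class", LETTERS[1 + (seq_len(members) - 1L) %% 5L])
  out <- vector("list", n_libraries)
  for (i in seq_len(n_libraries)) {
    lib_id <- sprintf("lib%04d", i)
    lib_seed <- derive_seed(lib_id, seed)
    lib <- .with_seed(lib_seed, {
      conc <- stats::rlnorm(members, conc_meanlog, conc_sdlog)
      if (balance[i] == "balanced") conc <- pmin(conc, cap)
      pick <- sample.int(nrow(prof), members, replace = TRUE,
                         prob = profile_probs)
      depth <- round(exp(stats::runif(1, log(depth_range[1]),
                                      log(depth_range[2]))))
      list(conc = conc, pick = pick, depth = depth)
    })
    eff <- mismatch_to_efficiency(prof[lib$pick, 1L], prof[lib$pick, 2L],
                                  params)
    mem <- data.frame(concentration = lib$conc, efficiency = eff)
    props <- simulate_amplification(mem, cycles)
    run <- sample_reads(props, lib$depth, seed = lib_seed + 1L)
    out[[i]] <- data.frame(
      library_id = lib_id,
      taxon_id = sprintf("taxon%03d", seq_len(members)),
      class = classes,
      concentration = lib$conc,
      rel_conc = lib$conc / sum(lib$conc),
      m3 = prof[lib$pick, 1L], m5 = prof[lib$pick, 2L],
      efficiency = eff, proportion = props,
      count = run$counts, detected = detect(run, r_min),
      depth = lib$depth, seed = lib_seed,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

# ridge-penalized logistic IRLS; fallback when glm meets complete
# separation. Penalty excluded from the intercept.
.ridge_logistic <- function(X, y, lambda = 1e-2, maxit = 100L) {
  beta <- rep(0, ncol(X))
  pen <- diag(c(0, rep(lambda, ncol(X) - 1L)))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    H <- XtW %*% X + pen
    beta_new <- drop(solve(H, XtW %*% z))
    if (max(abs(beta_new - beta)) < 1e-10) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  se <- sqrt(diag(solve(H)))
  list(coefficients = stats::setNames(beta, colnames(X)),
       se = stats::setNames(se, colnames(X)))
}

#' Fit the binomial detection-probability model
#'
#' Logistic regression of per-member detection on log relative template
#' concentration and log sequencing depth, by default with their
#' interaction and with covariates centered (so main effects are average
#' effects over the observed depth range; centers are stored and undone
#' in prediction). Reports coefficients, standard errors, McFadden
#' pseudo-R-squared (1 - loglik/loglik_null), and a prediction grid over
#' relative concentration x depth. Complete separation is flagged and a
#' ridge-penalized fit substituted (labeled).
#'
#' @param observations data.frame with columns `detected` (logical),
#'   `rel_conc` (> 0), `depth` (> 0), e.g. from [simulate_experiment()].
#' @param interaction include the interaction term (default `TRUE`).
#' @param center center the log covariates (default `TRUE`).
#' @param grid_rel_conc,grid_depth prediction-grid axes.
#' @return object of class `detection_fit`: `coefficients`, `se`, `p`,
#'   `mcfadden_r2`, `n`, `centers`, `interaction`, `separation`,
#'   `penalized`, `grid` (data.frame `rel_conc`, `depth`,
#'   `p_detect`).
#' @export
fit_detection_model <- function(observations, interaction = TRUE,
                                center = TRUE,
                                grid_rel_conc = 10^seq(-4, 0, by = 0.25),
                                grid_depth = c(1e3, 1e4, 1e5)) {
  obs <- observations
  stopifnot(all(c("detected", "rel_conc", "depth") %in% names(obs)),
            all(obs$rel_conc > 0), all(obs$depth > 0),
            all(is.finite(log(obs$rel_conc))), all(is.finite(log(obs$depth))))
  y <- as.numeric(obs$detected)
  if (length(unique(y)) < 2L) {
    stop("detection outcomes are constant; model is not identifiable",
         call. = FALSE)
  }
  centers <- if (center) {
    c(log_rel_conc = mean(log(obs$rel_conc)), log_depth = mean(log(obs$depth)))
  } else {
    c(log_rel_conc = 0, log_depth = 0)
  }
  x1 <- log(obs$rel_conc) - centers["log_rel_conc"]
  x2 <- log(obs$depth) - centers["log_depth"]
  dat <- data.frame(y = y, log_rel_conc = x1, log_depth = x2)
  form <- if (interaction) y ~ log_rel_conc * log_depth
          else y ~ log_rel_conc + log_depth
  warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w)))
        warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  mu <- stats::fitted(fit)
  separation <- warned && (!fit$converged || all(abs(mu - y) < 1e-6))
  penalized <- FALSE
  if (separation) {
    X <- stats::model.matrix(form, dat)
    rf <- .ridge_logistic(X, y)
    coefs <- rf$coefficients
    se <- rf$se
    penalized <- TRUE
    eta_hat <- drop(X %*% coefs)
    ll <- sum(y * eta_hat - log1p(exp(eta_hat)))
  } else {
    co <- summary(fit)$coefficients
    # aliased (e.g. constant-covariate) terms: coefficient 0, no SE
    all_terms <- names(stats::coef(fit))
    coefs <- stats::setNames(rep(0, length(all_terms)), all_terms)
    se <- stats::setNames(rep(NA_real_, length(all_terms)), all_terms)
    got <- intersect(rownames(co), all_terms)
    coefs[got] <- co[got, "Estimate"]
    se[got] <- co[got, "Std. Error"]
    ll <- as.numeric(stats::logLik(fit))
  }
  p0 <- mean(y)
  ll_null <- sum(y * log(p0) + (1 - y) * log(1 - p0))
  mcfadden <- 1 - ll / ll_null
  pvals <- 2 * stats::pnorm(-abs(coefs / se))
  predict_fun <- function(rel_conc, depth) {
    z1 <- log(rel_conc) - centers["log_rel_conc"]
    z2 <- log(depth) - centers["log_depth"]
    eta <- coefs[["(Intercept)"]] + coefs[["log_rel_conc"]] * z1 +
      coefs[["log_depth"]] * z2
    if (interaction) eta <- eta + coefs[["log_rel_conc:log_depth"]] * z1 * z2
    stats::plogis(unname(eta))
  }
  grid <- expand.grid(rel_conc = grid_rel_conc, depth = grid_depth,
                      KEEP.OUT.ATTRS = FALSE)
  grid$p_detect <- predict_fun(grid$rel_conc, grid$depth)
  structure(
    list(coefficients = coefs, se = se, p = pvals,
         mcfadden_r2 = mcfadden, n = length(y), centers = centers,
         interaction = interaction, separation = separation,
         penalized = penalized, grid = grid, predict = predict_fun),
    class = "detection_fit")
}

#' Predict detection probability from a fitted detection model
#'
#' @param object a `detection_fit`.
#' @param rel_conc,depth covariate values (vectorized, recycled).
#' @param ... unused.
#' @return detection probabilities.
#' @export
predict.detection_fit <- function(object, rel_conc, depth, ...) {
  object$predict(rel_conc, depth)
}

#' @export
print.detection_fit <- function(x, ...) {
  cat(sprintf("<detection_fit> n=%d, McFadden R2=%.3f%s%s\n", x$n,
              x$mcfadden_r2,
              if (x$separation) ", separation flagged" else "",
              if (x$penalized) " (ridge-penalized fit)" else ""))
  print(data.frame(estimate = x$coefficients, se = x$se, p = x$p),
        digits = 4)
  invisible(x)
}
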