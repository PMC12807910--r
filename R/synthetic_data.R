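# Synthetic experiments with the structure the analysis assumes: a signed
# SOA grid with per-SOA trial counts, lognormal between-participant capacity,
# condition-level probe weights, categorization queries with class-specific
# accuracy, sparse use of a deferred ("show again later") response, and an
# optional fraction of careless responders who answer at chance everywhere.

# one 60 Hz frame, stored exactly
FRAME_MS <- 50 / 3

#' Experimental design: SOA grid and trial counts
#'
#' The default grids mirror the two study designs this package emulates:
#' seven signed SOAs at one-frame resolution on a 60 Hz display
#' (-100, -50, -50/3, 0, 50/3, 50, 100 ms), with 20 trials per SOA per
#' condition in experiment 1 and counts (28, 40, 48, 48, 48, 40, 28) in
#' experiment 2 (280 TOJ trials per condition per participant).
#'
#' @param experiment 1 or 2; selects the default grid, counts and condition
#'   labels.
#' @param n_participants number of simulated participants.
#' @param soa_grid signed SOAs in ms (overrides the default).
#' @param trials_per_soa integer trial counts, one per SOA (overrides the
#'   default; applied to every condition).
#' @param conditions character vector of condition labels.
#' @return object of class `design_spec`.
#' @export
design_spec <- function(experiment = 2,
                        n_participants = if (experiment == 1) 32 else 49,
                        soa_grid = NULL, trials_per_soa = NULL,
                        conditions = NULL) {
  stopifnot(experiment %in% c(1, 2))
  if (n_participants <= 0) stop("n_participants must be positive")
  if (is.null(soa_grid)) {
    soa_grid <- c(-100, -50, -FRAME_MS, 0, FRAME_MS, 50, 100)
  }
  if (is.null(trials_per_soa)) {
    trials_per_soa <- if (experiment == 1) rep(20L, 7L)
                      else c(28L, 40L, 48L, 48L, 48L, 40L, 28L)
  }
  if (length(trials_per_soa) != length(soa_grid)) {
    stop("trials_per_soa must have one count per SOA")
  }
  if (any(trials_per_soa < 0)) stop("trial counts must be non-negative")
  if (is.null(conditions)) {
    conditions <- if (experiment == 1) c("BlueBlue", "RedRed", "BlueRed")
                  else c("2correct", "2false", "1each")
  }
  structure(list(experiment = experiment,
                 n_participants = as.integer(n_participants),
                 soa_grid = soa_grid,
                 trials_per_soa = as.integer(trials_per_soa),
                 conditions = conditions),
            class = "design_spec")
}

#' Population-level generating parameters
#'
#' Capacities are lognormal across participants:
#' \eqn{C_i = \exp(C_\mu + C_\sigma z_i)} with standard-normal \eqn{z_i},
#' shared across conditions unless `C_mu` is a named per-condition vector.
#' Weights are condition-level constants, optionally jittered per participant
#' by a Beta distribution centred on the condition value.
#'
#' Defaults emulate the experiment-2 study conditions: capacities near
#' 110 Hz (C_mu = log(0.11) per ms) with moderate between-participant spread,
#' weights at 0.5 in every condition, and a small careless fraction (2 of 51
#' recruited participants responded at chance).
#'
#' @param C_mu location of log capacity (log events/ms); scalar or named by
#'   condition.
#' @param C_sigma standard deviation of log capacity, >= 0.
#' @param w_by_condition named numeric vector, probe weight per condition,
#'   each in (0, 1).
#' @param w_concentration if finite, per-participant weights are drawn from
#'   Beta(w k, (1-w) k) with this concentration k; `Inf` (default) means no
#'   jitter.
#' @param careless_fraction proportion of participants responding at chance,
#'   in [0, 1].
#' @return object of class `population_spec`.
#' @export
population_spec <- function(C_mu = log(0.11), C_sigma = 0.3,
                            w_by_condition = c(`2correct` = 0.5,
                                               `2false` = 0.5,
                                               `1each` = 0.5),
                            w_concentration = Inf,
                            careless_fraction = 2 / 51) {
  if (C_sigma < 0) stop("C_sigma must be >= 0")
  if (any(w_by_condition <= 0) || any(w_by_condition >= 1)) {
    stop("weights must lie strictly in (0, 1)")
  }
  if (careless_fraction < 0 || careless_fraction > 1) {
    stop("careless_fraction must lie in [0, 1]")
  }
  structure(list(C_mu = C_mu, C_sigma = C_sigma,
                 w_by_condition = w_by_condition,
                 w_concentration = w_concentration,
                 careless_fraction = careless_fraction),
            class = "population_spec")
}

#' Draw per-participant attention parameters
#'
#' Instantiates the generative direction of the hierarchical model: each
#' participant's capacity is a lognormal draw, and each (participant,
#' condition) cell carries a probe weight from the population spec.
#'
#' @param pop a [population_spec()].
#' @param design a [design_spec()].
#' @param seed integer seed; identical seeds give identical output.
#' @return data frame with columns `participant`, `condition`, `C` (events/
#'   ms), `w`, and `careless` (logical, constant within participant).
#' @export
simulate_participants <- function(pop, design, seed = 1L) {
  stopifnot(inherits(pop, "population_spec"), inherits(design, "design_spec"))
  conds <- design$conditions
  if (!all(conds %in% names(pop$w_by_condition)) &&
      length(pop$w_by_condition) != length(conds)) {
    stop("w_by_condition must cover every design condition")
  }
  w_cond <- if (all(conds %in% names(pop$w_by_condition))) {
    pop$w_by_condition[conds]
  } else stats::setNames(rep_len(pop$w_by_condition, length(conds)), conds)
  C_mu <- if (!is.null(names(pop$C_mu)) && all(conds %in% names(pop$C_mu))) {
    pop$C_mu[conds]
  } else stats::setNames(rep_len(pop$C_mu, length(conds)), conds)

  n <- design$n_participants
  withr_seed(seed, {
    z <- stats::rnorm(n)
    n_careless <- round(pop$careless_fraction * n)
    careless <- rep(FALSE, n)
    if (n_careless > 0) careless[sample.int(n, n_careless)] <- TRUE
    out <- do.call(rbind, lapply(conds, function(cc) {
      w <- if (is.finite(pop$w_concentration)) {
        k <- pop$w_concentration
        stats::rbeta(n, w_cond[[cc]] * k, (1 - w_cond[[cc]]) * k)
      } else rep(w_cond[[cc]], n)
      data.frame(participant = sprintf("p%02d", seq_len(n)),
                 condition = cc,
                 C = exp(C_mu[[cc]] + pop$C_sigma * z),
                 w = w,
                 careless = careless,
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}

# run expr under a temporary RNG state seeded by `seed`, restoring the
# caller's state afterwards (keeps simulation functions referentially
# transparent in seed)
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Simulate temporal-order judgment trials
#'
#' For every (participant, condition, SOA) cell, draws the probe-first count
#' from a binomial with the closed-form race probability, then expands to one
#' row per trial. Careless participants respond Bernoulli(0.5) at every SOA
#' instead.
#'
#' @param params data frame from [simulate_participants()].
#' @param design a [design_spec()].
#' @param seed integer seed.
#' @return data frame of trials with columns `participant`, `experiment`,
#'   `condition`, `soa_ms`, `probe_first`, `careless_truth`.
#' @export
simulate_trials <- function(params, design, seed = 1L) {
  stopifnot(inherits(design, "design_spec"))
  need <- expand.grid(participant = unique(params$participant),
                      condition = design$conditions,
                      stringsAsFactors = FALSE)
  key <- paste(params$participant, params$condition)
  if (!all(paste(need$participant, need$condition) %in% key)) {
    stop("params must cover every (participant, condition) pair")
  }
  cells <- merge(params,
                 expand.grid(condition = design$conditions,
                             soa_idx = seq_along(design$soa_grid),
                             stringsAsFactors = FALSE),
                 by = "condition")
  cells$soa_ms <- design$soa_grid[cells$soa_idx]
  cells$n <- design$trials_per_soa[cells$soa_idx]
  cells <- cells[order(cells$participant, cells$condition, cells$soa_ms), ]
  withr_seed(seed, {
    p <- ifelse(cells$careless, 0.5,
                p_probe_first_cw(cells$C, cells$w, cells$soa_ms))
    k <- stats::rbinom(nrow(cells), cells$n, p)
    idx <- rep(seq_len(nrow(cells)), cells$n)
    resp <- unlist(lapply(seq_len(nrow(cells)), function(i) {
      sample(c(rep(1L, k[i]), rep(0L, cells$n[i] - k[i])))
    }), use.names = FALSE)
    data.frame(participant = cells$participant[idx],
               experiment = design$experiment,
               condition = cells$condition[idx],
               soa_ms = cells$soa_ms[idx],
               probe_first = resp,
               careless_truth = cells$careless[idx],
               stringsAsFactors = FALSE)
  })
}

#' Difficulty model for categorization queries
#'
#' Accuracy of the type-categorization judgment per stimulus class. The
#' default reproduces the ordering observed in the study: blue forms easier
#' than red, and for red forms an extreme width-to-height ratio easier than a
#' near-1 ratio.
#'
#' @param accuracy named numeric vector with entries `blue_easy`,
#'   `blue_hard`, `red_easy`, `red_hard`, each in [0, 1].
#' @return object of class `difficulty_model`.
#' @export
difficulty_model <- function(accuracy = c(blue_easy = 0.7025,
                                          blue_hard = 0.6832,
                                          red_easy = 0.6791,
                                          red_hard = 0.5703)) {
  need <- c("blue_easy", "blue_hard", "red_easy", "red_hard")
  if (!all(need %in% names(accuracy))) {
    stop("accuracy must name blue_easy, blue_hard, red_easy, red_hard")
  }
  if (any(accuracy < 0) || any(accuracy > 1)) {
    stop("accuracies must lie in [0, 1]")
  }
  structure(list(accuracy = accuracy[need]), class = "difficulty_model")
}

#' Attach categorization-query outcomes to trials
#'
#' Marks a fraction of trials as query trials (all of them for the
#' experiment-2 procedure, where every TOJ is followed by a classification
#' judgment), assigns each queried form a stimulus class, and draws the
#' correctness of the response Bernoulli with the class-specific accuracy.
#'
#' @param trials trial table from [simulate_trials()].
#' @param model a [difficulty_model()].
#' @param query_fraction fraction of trials carrying a query; default 0.25
#'   for experiment 1 and 1 for experiment 2.
#' @param seed integer seed.
#' @return `trials` with added columns `is_query_trial`, `stimulus_color`,
#'   `ratio_difficulty`, `query_correct` (NA on non-query trials).
#' @export
simulate_queries <- function(trials, model = difficulty_model(),
                             query_fraction = NULL, seed = 1L) {
  stopifnot(inherits(model, "difficulty_model"))
  if (is.null(query_fraction)) {
    query_fraction <- if (all(trials$experiment == 1)) 0.25 else 1
  }
  if (query_fraction < 0 || query_fraction > 1) {
    stop("query_fraction must lie in [0, 1]")
  }
  withr_seed(seed, {
    n <- nrow(trials)
    is_q <- stats::runif(n) < query_fraction
    color <- sample(c("blue", "red"), n, replace = TRUE)
    diffi <- sample(c("easy", "hard"), n, replace = TRUE)
    acc <- model$accuracy[paste(color, diffi, sep = "_")]
    trials$is_query_trial <- is_q
    trials$stimulus_color <- ifelse(is_q, color, NA_character_)
    trials$ratio_difficulty <- ifelse(is_q, diffi, NA_character_)
    qc <- ifelse(is_q, stats::rbinom(n, 1L, acc), NA_integer_)
    trials$query_correct <- as.integer(qc)
    trials
  })
}

#' Overwrite designated participants' responses with chance responding
#'
#' Emulates careless responders: for the given fraction of participants
#' (sampled by seed, or those already flagged `careless_truth`), every
#' probe-first response is replaced by an independent Bernoulli(0.5) draw,
#' making order judgments uninformative at every SOA.
#'
#' @param trials trial table.
#' @param fraction proportion of participants to convert; if `NULL`, uses the
#'   existing `careless_truth` flags.
#' @param seed integer seed.
#' @return trial table with responses replaced and `careless_truth` updated.
#' @export
inject_careless <- function(trials, fraction = NULL, seed = 1L) {
  withr_seed(seed, {
    if (!is.null(fraction)) {
      if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
      ids <- unique(trials$participant)
      n_c <- round(fraction * length(ids))
      chosen <- if (n_c > 0) sample(ids, n_c) else character(0)
      trials$careless_truth <- trials$participant %in% chosen
    }
    sel <- trials$careless_truth
    trials$probe_first[sel] <- stats::rbinom(sum(sel), 1L, 0.5)
    trials
  })
}

#' Attach sparse "show again later" usage
#'
#' A minority of participants ever defers a classification judgment; those
#' who do, do so rarely. Usage is Bernoulli per query opportunity at a
#' per-participant rate that is zero for most participants.
#'
#' @param trials trial table with query columns.
#' @param user_fraction fraction of participants with a nonzero deferral
#'   rate (default 12/49, the sparsity the summaries are tested against).
#' @param mean_rate mean per-opportunity deferral rate among users.
#' @param seed integer seed.
#' @return trial table with added integer column `sal_used` (NA off query
#'   trials).
#' @export
simulate_sal <- function(trials, user_fraction = 12 / 49,
                         mean_rate = 0.024, seed = 1L) {
  withr_seed(seed, {
    ids <- unique(trials$participant)
    n_users <- round(user_fraction * length(ids))
    users <- if (n_users > 0) sample(ids, n_users) else character(0)
    rate <- stats::setNames(rep(0, length(ids)), ids)
    if (n_users > 0) {
      rate[users] <- stats::rexp(n_users, 1 / mean_rate)
    }
    r <- rate[trials$participant]
    on_q <- !is.na(trials$is_query_trial) & trials$is_query_trial
    sal <- ifelse(on_q, stats::rbinom(nrow(trials), 1L, pmin(r, 1)),
                  NA_integer_)
    trials$sal_used <- as.integer(sal)
    trials
  })
}

#' Simulate a complete synthetic experiment
#'
#' Convenience wrapper chaining participants, TOJ trials, categorization
#' queries, careless responding, and deferral usage, with sub-seeds derived
#' from one master seed.
#'
#' @param pop a [population_spec()].
#' @param design a [design_spec()].
#' @param seed master integer seed.
#' @param queries,sal logical; attach query outcomes / deferral usage.
#' @return list with elements `params` (true per-participant parameters) and
#'   `trials` (the trial table).
#' @export
simulate_experiment <- function(pop = population_spec(),
                                design = design_spec(),
                                seed = 1L, queries = TRUE, sal = TRUE) {
  seeds <- derive_seeds(seed, 4)
  params <- simulate_participants(pop, design, seeds[1])
  trials <- simulate_trials(params, design, seeds[2])
  if (queries) trials <- simulate_queries(trials, seed = seeds[3])
  trials <- inject_careless(trials, fraction = NULL, seed = seeds[2])
  if (sal && queries) trials <- simulate_sal(trials, seed = seeds[4])
  list(params = params, trials = trials)
}

# derive k reproducible 31-bit sub-seeds from one master seed
derive_seeds <- function(seed, k) {
  withr_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}
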