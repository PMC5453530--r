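## Synthetic world: attributed populations, planted tie graphs, and
## check-in event streams with the statistical structure the co-occurrence
## test assumes (multi-location check-ins, strong daily peak hours,
## heterogeneous subject activity, ties biased by categorical attributes).
## Everything is seeded and deterministic, so end-to-end pipelines can be
## validated without any real data.

# ---- population ------------------------------------------------------------

#' Specify a synthetic population
#'
#' @param n number of subjects.
#' @param attributes named list of categorical attribute specs; each entry
#'   is a named numeric vector of label fractions summing to 1. The default
#'   emulates a student cohort: a binary gender split and four equal grade
#'   levels.
#' @return a `population_spec`.
#' @export
population_spec <- function(n = 200L,
                            attributes = list(
                              gender = c(Male = 0.5, Female = 0.5),
                              grade = c(Freshman = 0.25, Sophomore = 0.25,
                                        Junior = 0.25, Senior = 0.25))) {
  if (!is_count(n) || n < 1) {
    svcn_abort("parameter_error", "n must be a positive integer")
  }
  for (an in names(attributes)) {
    fr <- attributes[[an]]
    if (is.null(names(fr)) || any(fr < 0) ||
        abs(sum(fr) - 1) > 1e-8) {
      svcn_abort("parameter_error",
                 sprintf("fractions for '%s' must be named, >= 0, sum to 1",
                         an))
    }
  }
  structure(list(n = as.integer(n), attributes = attributes),
            class = "population_spec")
}

#' Generate an attributed population
#'
#' Labels are drawn independently per subject from the spec fractions, so
#' observed marginals match the spec within binomial sampling error.
#'
#' @param spec a `population_spec`.
#' @param seed integer seed (same seed, same population).
#' @return an `attribute_table` with subject ids `s0001, s0002, ...`.
#' @export
gen_population <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n
  ids <- sprintf("s%05d", seq_len(n))
  df <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  withr_seed(seed, {
    for (an in names(spec$attributes)) {
      fr <- spec$attributes[[an]]
      df[[an]] <- sample(names(fr), n, replace = TRUE, prob = fr)
    }
  })
  attribute_table(df)
}

# ---- planted tie graph -----------------------------------------------------

#' Specify the planted tie model
#'
#' Dyads are independent Bernoulli draws; a pair sharing the label of
#' attribute `a` has its tie probability multiplied by `beta[a]`
#' (`beta = 1` everywhere gives an Erdos-Renyi dyad process).
#'
#' @param p_base baseline tie probability for a pair sharing no attribute.
#' @param beta named vector of intra-group multipliers (>= 0) per
#'   attribute; attributes not named have multiplier 1.
#' @param mean_degree optional target mean degree; when given, all dyad
#'   probabilities are rescaled so the expected mean degree matches it.
#' @return a `tie_model`.
#' @export
tie_model <- function(p_base = 0.01, beta = c(grade = 4), mean_degree = NULL) {
  if (!is.numeric(p_base) || p_base < 0 || p_base > 1) {
    svcn_abort("parameter_error", "p_base must be in [0, 1]")
  }
  if (length(beta) && (is.null(names(beta)) || any(beta < 0))) {
    svcn_abort("parameter_error", "beta must be a named non-negative vector")
  }
  structure(list(p_base = p_base, beta = beta, mean_degree = mean_degree),
            class = "tie_model")
}

#' Generate a ground-truth tie graph
#'
#' @param population an `attribute_table` (e.g. from [gen_population()]).
#' @param model a `tie_model`.
#' @param seed integer seed.
#' @return an undirected `igraph` graph over all subjects (isolates kept).
#' @export
gen_tie_graph <- function(population, model, seed = 1L) {
  stopifnot(inherits(population, "attribute_table"),
            inherits(model, "tie_model"))
  ids <- population$subject_id
  n <- length(ids)
  ut <- upper.tri(matrix(0, n, n))
  p <- matrix(model$p_base, n, n)
  for (an in names(model$beta)) {
    if (!an %in% names(population)) {
      svcn_abort("parameter_error",
                 sprintf("beta names attribute '%s' absent from population",
                         an))
    }
    v <- population[[an]]
    same <- outer(v, v, "==")
    p[same] <- p[same] * model$beta[[an]]
  }
  if (!is.null(model$mean_degree)) {
    exp_deg <- 2 * sum(p[ut]) / n
    if (exp_deg > 0) p <- p * (model$mean_degree / exp_deg)
  }
  if (any(p[ut] > 1)) {
    svcn_abort("parameter_error",
               "tie probabilities exceed 1; reduce p_base or beta")
  }
  draw <- withr_seed(seed, matrix(runif(n * n), n, n))
  adj <- ut & (draw < p)
  idx <- which(adj, arr.ind = TRUE)
  graph_from_edges(ids[idx[, 1L]], ids[idx[, 2L]], nodes = ids)
}

# ---- check-in event stream -------------------------------------------------

#' Specify the check-in generating process
#'
#' @param n_locations number of check-in locations (default 17: the scale
#'   of a campus's canteens and stores).
#' @param n_days study length in days.
#' @param visits_per_day mean check-ins per subject per day; per-subject
#'   rates are Gamma-distributed around it (activity heterogeneity).
#' @param activity_shape Gamma shape of the per-subject rate (smaller =
#'   more heterogeneous; default 4).
#' @param peak_hours,peak_weights,peak_sd_hours daily time-of-day mixture:
#'   Gaussian bumps at meal hours (default 07:30, 12:00, 18:30), truncated
#'   to `[5, 23.5]` hours.
#' @param location_concentration Dirichlet concentration of each subject's
#'   location-preference distribution (small values = subjects loyal to a
#'   few locations). Default 1, the flat Dirichlet: preferences vary
#'   across subjects yet remain diffuse enough that the size-weighted
#'   random-appearance null stays approximately calibrated, which is the
#'   operating regime the co-occurrence test assumes.
#' @param rho per tied pair per day, the probability that the two subjects
#'   make a synchronized co-visit (same location, same timeslot). `rho = 0`
#'   gives a tie-free null stream.
#' @param tau timeslot length (seconds) used for co-visit synchronization;
#'   must divide 86400 so slots align with midnight-origin binning.
#' @param start_date first day of the study window (UTC date).
#' @return a `checkin_model`.
#' @export
checkin_model <- function(n_locations = 17L, n_days = 30L,
                          visits_per_day = 2.5, activity_shape = 4,
                          peak_hours = c(7.5, 12, 18.5),
                          peak_weights = c(0.25, 0.40, 0.35),
                          peak_sd_hours = 0.6,
                          location_concentration = 1,
                          rho = 0, tau = 300,
                          start_date = "2015-09-01") {
  if (!is.numeric(rho) || rho < 0 || rho > 1) {
    svcn_abort("parameter_error", "rho must be in [0, 1]")
  }
  if (visits_per_day <= 0 || activity_shape <= 0 ||
      location_concentration <= 0 || peak_sd_hours <= 0) {
    svcn_abort("parameter_error", "rates and spreads must be positive")
  }
  if (86400 %% tau != 0) {
    svcn_abort("parameter_error", "tau must divide 86400 seconds")
  }
  if (length(peak_hours) != length(peak_weights) ||
      abs(sum(peak_weights) - 1) > 1e-8) {
    svcn_abort("parameter_error",
               "peak_weights must match peak_hours and sum to 1")
  }
  structure(list(n_locations = as.integer(n_locations),
                 n_days = as.integer(n_days),
                 visits_per_day = visits_per_day,
                 activity_shape = activity_shape,
                 peak_hours = peak_hours, peak_weights = peak_weights,
                 peak_sd_hours = peak_sd_hours,
                 location_concentration = location_concentration,
                 rho = rho, tau = tau, start_date = start_date),
            class = "checkin_model")
}

#' Generate a synthetic check-in event stream
#'
#' Each subject draws a daily number of visits from its own Poisson rate,
#' visit times from the peak-hour mixture and locations from its preference
#' distribution. For each tied pair, on each day with probability `rho`
#' one randomly chosen visit of one subject is overwritten to match a
#' randomly chosen visit of the other (same location, a time within the
#' same `tau` slot) — overwriting rather than adding keeps per-subject
#' activity rates independent of `rho`.
#'
#' @param population an `attribute_table` of subjects.
#' @param ties an `igraph` graph of ground-truth ties (may be edgeless),
#'   or `NULL` for a tie-free stream.
#' @param model a `checkin_model`.
#' @param seed integer seed; the whole stream is a deterministic function
#'   of (population, ties, model, seed).
#' @return an `event_stream` sorted by timestamp.
#' @export
gen_events <- function(population, ties = NULL, model = checkin_model(),
                       seed = 1L) {
  stopifnot(inherits(population, "attribute_table"),
            inherits(model, "checkin_model"))
  ids <- population$subject_id
  n <- length(ids)
  nd <- model$n_days
  L <- model$n_locations
  origin <- as.numeric(as.POSIXct(paste(model$start_date, "00:00:00"),
                                  tz = "UTC"))
  withr_seed(seed, {
    rate <- rgamma(n, shape = model$activity_shape,
                   rate = model$activity_shape / model$visits_per_day)
    pref <- matrix(rgamma(n * L, shape = model$location_concentration), n, L)
    pref <- pref / rowSums(pref)
    cum_pref <- t(apply(pref, 1L, cumsum))

    counts <- matrix(rpois(n * nd, rep(rate, nd)), n, nd)  # [subject, day]
    total <- sum(counts)
    if (total == 0L) {
      return(event_stream(character(), numeric(), character()))
    }
    ## one row per visit, ordered by (subject, day): row offsets let the
    ## synchronization step index a random visit of (subject, day) in O(1)
    subj <- rep(rep(seq_len(n), nd), as.vector(counts))  # day-major here
    day <- rep(rep(seq_len(nd), each = n), as.vector(counts))
    ord <- order(subj, day)
    subj <- subj[ord]; day <- day[ord]
    comp <- sample.int(length(model$peak_hours), total, replace = TRUE,
                       prob = model$peak_weights)
    hour <- model$peak_hours[comp] + rnorm(total, 0, model$peak_sd_hours)
    hour <- pmin(pmax(hour, 5), 23.5)
    tsec <- origin + (day - 1) * 86400 + floor(hour * 3600)
    u <- runif(total)
    loc <- rowSums(u > cum_pref[subj, , drop = FALSE]) + 1L

    rho <- model$rho
    if (!is.null(ties) && rho > 0 && igraph::ecount(ties) > 0) {
      start_sd <- matrix(cumsum(c(1L, head(as.vector(t(counts)), -1L))),
                         n, nd, byrow = TRUE)  # row offsets in (subj, day)
      el <- igraph::as_edgelist(ties, names = TRUE)
      e1 <- match(el[, 1L], ids)
      e2 <- match(el[, 2L], ids)
      ok <- !is.na(e1) & !is.na(e2)
      e1 <- e1[ok]; e2 <- e2[ok]
      ne <- length(e1)
      if (ne) {
        act <- runif(ne * nd) < rho
        pe <- rep(seq_len(ne), nd)[act]   # tie index of each sync attempt
        pd <- rep(seq_len(nd), each = ne)[act]  # its day
        ns <- length(pe)
        if (ns) {
          flip <- runif(ns) < 0.5  # which endpoint anchors
          anc_s <- ifelse(flip, e1[pe], e2[pe])
          tgt_s <- ifelse(flip, e2[pe], e1[pe])
          ## each visit may serve at most one synchronization role per day,
          ## otherwise two partners anchored to the same visit co-occur
          ## systematically and plant spurious triadic ties; syncs beyond a
          ## subject's visit count that day are skipped
          roles <- data.table::data.table(
            sync = rep(seq_len(ns), 2L),
            s = c(anc_s, tgt_s), d = c(pd, pd),
            shuffle = runif(2L * ns))
          data.table::setorder(roles, shuffle)
          roles[, k := seq_len(.N), by = c("s", "d")]
          roles[, feasible := k <= counts[cbind(s, d)]]
          oks <- roles[, list(all_ok = all(feasible)), by = "sync"]
          good <- oks$sync[oks$all_ok]
          roles <- roles[roles$sync %in% good]
          roles[, row := start_sd[cbind(s, d)] + k - 1L]
          data.table::setorder(roles, sync)
          is_anchor <- roles$s == anc_s[roles$sync]
          ## ties with identical endpoints impossible (simple graph), so
          ## each sync has exactly one anchor and one target row
          anc_row <- roles$row[is_anchor]
          tgt_row <- roles$row[!is_anchor]
          slot <- floor(tsec[anc_row] / model$tau)
          loc[tgt_row] <- loc[anc_row]
          tsec[tgt_row] <- slot * model$tau +
            floor(runif(length(tgt_row)) * model$tau)
        }
      }
    }
    o <- order(tsec, subj)
    event_stream(ids[subj[o]], tsec[o], sprintf("loc%02d", loc[o]))
  })
}
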