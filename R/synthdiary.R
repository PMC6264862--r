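#' Default symptom list
#'
#' Ten common childhood illness symptoms. The first eight are the classic
#' respiratory/atopic diary items; the last two are configurable
#' placeholders for rarer items.
#'
#' @export
default_symptoms <- function() {
  c("cough", "cold", "wheeze", "eczema", "fever",
    "gastric", "earinfection", "pneumonia", "croup", "conjunctivitis")
}

#' Configuration for a simulated diary cohort
#'
#' Each symptom is generated by a two-state (absent/present) Markov chain:
#' the daily onset probability is `plogis(mu + class shift + A * cos(2 *
#' pi * (d - phi) / 365.25) + coupling)`, with `d` the day of the calendar
#' year, and the day-to-day persistence of an ongoing symptom is `p_stay`.
#' A latent child class shifts the onset log-odds per symptom
#' (e.g. a respiratory-dominant class raises cough/cold/wheeze onset, an
#' eczema-dominant class raises eczema onset). A shared latent infection
#' episode — itself a seasonal two-state chain — adds `coupling` to the
#' onset log-odds of the respiratory triad (cough, cold, fever), producing
#' multi-day co-occurring illness episodes.
#'
#' Missingness is applied after symptom generation and independently of
#' it: a daily dropout hazard with spikes at half-year ages (days 182,
#' 365, 548, 730, 913, 1095 from enrolment) truncates participation, and
#' short random gaps blank whole days inside the participation window.
#' The default hazard is calibrated so that about 10 percent of children
#' have left the study by age 2.5 years (day 913).
#'
#' @param n_children Number of children.
#' @param symptoms Ordered symptom names; the order defines pattern codes.
#' @param enrolment_window Length-2 `Date` vector; enrolment dates are
#'   drawn uniformly from this range.
#' @param follow_up_days Target follow-up length in days (3 years = 1096).
#' @param class_proportions Named probability vector over latent classes.
#' @param class_effects Numeric matrix (classes x symptoms) of onset
#'   log-odds shifts; rows must match `names(class_proportions)`.
#' @param mu,amplitude,phase,p_stay Per-symptom baseline onset log-odds,
#'   seasonal amplitude (log-odds), seasonal phase (peak day of calendar
#'   year) and persistence probability. Recycled to `length(symptoms)`.
#' @param coupling Log-odds added to onset of `coupled_symptoms` while the
#'   latent infection episode is active; 0 switches coupling off.
#' @param coupled_symptoms Symptoms driven by the shared episode process.
#' @param episode_mu,episode_amplitude,episode_phase,episode_stay
#'   Parameters of the latent infection-episode chain (same roles as the
#'   per-symptom parameters).
#' @param base_hazard Daily dropout hazard between spikes.
#' @param spike_hazard Extra dropout probability at each half-year age.
#' @param spike_days Ages (days from enrolment) of the hazard spikes.
#' @param gap_rate Daily probability that a short missingness gap starts.
#' @param gap_mean_length Mean gap length in days (geometric).
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @return An object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_children = 300,
                          symptoms = default_symptoms(),
                          enrolment_window = as.Date(c("2009-01-01",
                                                       "2011-04-30")),
                          follow_up_days = 1096,
                          class_proportions = c(respiratory = 0.40,
                                                eczema = 0.30,
                                                febrile = 0.30),
                          class_effects = NULL,
                          mu = NULL,
                          amplitude = NULL,
                          phase = NULL,
                          p_stay = NULL,
                          coupling = 1.5,
                          coupled_symptoms = c("cough", "cold", "fever"),
                          episode_mu = -3.2,
                          episode_amplitude = 0.8,
                          episode_phase = 15,
                          episode_stay = 0.80,
                          base_hazard = 4e-5,
                          spike_hazard = 0.013,
                          spike_days = c(182, 365, 548, 730, 913, 1095),
                          gap_rate = 0.002,
                          gap_mean_length = 3,
                          seed = 1L) {
  if (length(n_children) != 1 || n_children < 1) {
    stop("cohort_config: n_children must be a positive count")
  }
  if (length(symptoms) < 1) stop("cohort_config: empty symptom list")
  M <- length(symptoms)

  defaults <- default_symptom_params()
  pick <- function(given, field, fallback) {
    if (!is.null(given)) return(rep_len(given, M))
    out <- rep_len(fallback, M)
    known <- symptoms %in% rownames(defaults)
    out[known] <- defaults[symptoms[known], field]
    out
  }
  mu        <- pick(mu,        "mu",        -6.0)
  amplitude <- pick(amplitude, "amplitude",  0.5)
  phase     <- pick(phase,     "phase",     15)
  p_stay    <- pick(p_stay,    "p_stay",     0.8)

  if (abs(sum(class_proportions) - 1) > 1e-8) {
    stop("cohort_config: class_proportions must sum to 1")
  }
  if (any(class_proportions < 0)) {
    stop("cohort_config: class_proportions must be non-negative")
  }
  if (is.null(class_effects)) {
    class_effects <- default_class_effects(names(class_proportions), symptoms)
  }
  class_effects <- as.matrix(class_effects)
  if (!identical(rownames(class_effects), names(class_proportions)) ||
      ncol(class_effects) != M) {
    stop("cohort_config: class_effects must be classes x symptoms with ",
         "rownames matching class_proportions")
  }
  probs <- c(p_stay, episode_stay, base_hazard, spike_hazard, gap_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("cohort_config: probabilities must lie in [0, 1]")
  }
  if (follow_up_days < 1) stop("cohort_config: follow_up_days must be > 0")

  structure(list(
    n_children = as.integer(n_children), symptoms = symptoms,
    enrolment_window = as.Date(enrolment_window),
    follow_up_days = as.integer(follow_up_days),
    class_proportions = class_proportions, class_effects = class_effects,
    mu = mu, amplitude = amplitude, phase = phase, p_stay = p_stay,
    coupling = coupling, coupled_symptoms = coupled_symptoms,
    episode_mu = episode_mu, episode_amplitude = episode_amplitude,
    episode_phase = episode_phase, episode_stay = episode_stay,
    base_hazard = base_hazard, spike_hazard = spike_hazard,
    spike_days = as.integer(spike_days),
    gap_rate = gap_rate, gap_mean_length = gap_mean_length,
    seed = as.integer(seed)), class = "cohort_config")
}

# Baseline two-state-chain parameters per symptom. Onset log-odds and
# seasonal amplitudes are chosen so that stationary prevalences are in the
# range reported for paediatric diary cohorts: cold peaks near 30% of days
# in mid-winter and 5% in summer, eczema is near-aseasonal and persistent,
# pneumonia is rare.
default_symptom_params <- function() {
  p <- rbind(
    cough          = c(-3.60, 1.00,  15, 0.85),
    cold           = c(-3.46, 1.09,  15, 0.80),
    wheeze         = c(-5.20, 0.60,  15, 0.85),
    eczema         = c(-5.50, 0.10,  15, 0.97),
    fever          = c(-4.60, 0.70,  30, 0.60),
    gastric        = c(-5.00, 0.50,  45, 0.60),
    earinfection   = c(-5.80, 0.60,  30, 0.80),
    pneumonia      = c(-8.00, 0.60,  30, 0.85),
    croup          = c(-7.00, 0.80, 330, 0.70),
    conjunctivitis = c(-6.30, 0.40,  60, 0.75))
  colnames(p) <- c("mu", "amplitude", "phase", "p_stay")
  p
}

# Three latent phenotypes with distinct symptom directions: a
# respiratory-dominant class (cough/cold/wheeze), an eczema-dominant
# class, and a febrile/gastrointestinal class (fever/gastric/ear
# infection). Shifts are onset log-odds.
default_class_effects <- function(classes, symptoms) {
  eff <- matrix(0, nrow = length(classes), ncol = length(symptoms),
                dimnames = list(classes, symptoms))
  shift <- function(class, symptom, value) {
    if (class %in% classes && symptom %in% symptoms) {
      eff[class, symptom] <<- value
    }
  }
  shift("respiratory", "cough",  1.2)
  shift("respiratory", "cold",   1.0)
  shift("respiratory", "wheeze", 1.8)
  shift("respiratory", "fever",  0.4)
  shift("eczema", "eczema", 2.5)
  shift("febrile", "fever",        1.8)
  shift("febrile", "gastric",      1.8)
  shift("febrile", "earinfection", 1.2)
  eff
}

#' Simulate a diary cohort
#'
#' Generates one diary per child under the process described in
#' [cohort_config()], together with the ground truth needed for recovery
#' tests: latent class labels, enrolment dates, realized dropout days and
#' the per-day latent infection-episode states.
#'
#' @param config A [cohort_config()].
#' @return A list with elements `diaries` (list of [diary()] objects) and
#'   `truth` (list with `children`, a data frame of per-child labels, and
#'   `episodes`, a children x days 0/1 matrix of latent episode states).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_children
  M <- length(config$symptoms)
  D <- config$follow_up_days

  classes <- sample(names(config$class_proportions), n, replace = TRUE,
                    prob = config$class_proportions)
  w0 <- as.numeric(config$enrolment_window[1])
  w1 <- as.numeric(config$enrolment_window[2])
  enrol <- as.Date(floor(runif(n, w0, w1 + 1)), origin = "1970-01-01")

  # day-of-calendar-year for every child x day (drives seasonality)
  all_days <- outer(as.numeric(enrol), seq_len(D) - 1, "+")
  yday <- matrix(as.POSIXlt(as.Date(as.vector(all_days),
                                    origin = "1970-01-01"))$yday + 1L,
                 nrow = n, ncol = D)

  class_shift <- config$class_effects[classes, , drop = FALSE]  # n x M
  coupled <- config$symptoms %in% config$coupled_symptoms
  kappa <- config$coupling

  X <- array(0L, dim = c(n, D, M))
  E <- matrix(0L, nrow = n, ncol = D)
  two_pi <- 2 * pi

  # start every chain from its (quasi-)stationary law on the enrolment
  # day, so early diary days carry no healthy-start transient
  yd1 <- yday[, 1]
  p_e1 <- plogis(config$episode_mu + config$episode_amplitude *
                   cos(two_pi * (yd1 - config$episode_phase) / 365.25))
  e_state <- as.integer(runif(n) <
                          p_e1 / (p_e1 + 1 - config$episode_stay))
  stay_mat <- matrix(config$p_stay, n, M, byrow = TRUE)
  lo1 <- matrix(config$mu, n, M, byrow = TRUE) + class_shift +
    cos(two_pi * (outer(yd1, config$phase, "-")) / 365.25) *
      matrix(config$amplitude, n, M, byrow = TRUE)
  if (kappa != 0 && any(coupled)) {
    lo1[, coupled] <- lo1[, coupled] + kappa * e_state
  }
  p1 <- plogis(lo1)
  pi1 <- p1 / (p1 + 1 - stay_mat)
  pi1[!is.finite(pi1)] <- 0     # absorbing degenerate chains start off
  s_state <- matrix(as.integer(matrix(runif(n * M), n, M) < pi1), n, M)
  for (d in seq_len(D)) {
    season_e <- cos(two_pi * (yday[, d] - config$episode_phase) / 365.25)
    p_e <- plogis(config$episode_mu + config$episode_amplitude * season_e)
    u <- runif(n)
    e_state <- ifelse(e_state == 1L, as.integer(u < config$episode_stay),
                      as.integer(u < p_e))
    E[, d] <- e_state

    # onset log-odds: baseline + class shift + season + episode coupling
    season <- cos(two_pi * (outer(yday[, d], config$phase, "-")) / 365.25)
    lo <- matrix(config$mu, n, M, byrow = TRUE) + class_shift +
      season * matrix(config$amplitude, n, M, byrow = TRUE)
    if (kappa != 0 && any(coupled)) {
      lo[, coupled] <- lo[, coupled] + kappa * e_state
    }
    p_on <- plogis(lo)
    u <- matrix(runif(n * M), n, M)
    s_state <- ifelse(s_state == 1L, (u < stay_mat) + 0L,
                      (u < p_on) + 0L)
    X[, d, ] <- s_state
  }

  # dropout: an event at day d ends participation at day d - 1
  hazard <- rep(config$base_hazard, D)
  spikes <- config$spike_days[config$spike_days <= D]
  hazard[spikes] <- hazard[spikes] + config$spike_hazard
  ev <- matrix(runif(n * D), n, D) <
    matrix(hazard, n, D, byrow = TRUE)
  ev[, 1] <- FALSE
  dropout <- apply(ev, 1, function(e) {
    hit <- which(e)
    if (length(hit) == 0) D else hit[1] - 1L
  })

  diaries <- vector("list", n)
  ids <- sprintf("child%04d", seq_len(n))
  for (i in seq_len(n)) {
    P <- dropout[i]
    v <- matrix(X[i, seq_len(P), ], nrow = P, ncol = M)
    if (config$gap_rate > 0 && P > 1) {
      starts <- which(runif(P - 1) < config$gap_rate) + 1L
      if (length(starts) > 0) {
        lens <- 1L + stats::rgeom(length(starts),
                                  prob = 1 / config$gap_mean_length)
        gap_days <- unique(unlist(mapply(
          function(s, l) seq(s, min(s + l - 1L, P)), starts, lens,
          SIMPLIFY = FALSE)))
        v[gap_days, ] <- NA_integer_
      }
    }
    diaries[[i]] <- diary(ids[i], enrol[i] + seq_len(P) - 1, v,
                          config$symptoms)
  }

  truth <- list(
    children = data.frame(child_id = ids, class = classes,
                          enrolment = enrol, dropout_day = dropout,
                          stringsAsFactors = FALSE),
    episodes = E)
  list(diaries = diaries, truth = truth)
}

#' Periodic stationary prevalence of a seasonal two-state chain
#'
#' Numerical oracle for the marginal daily prevalence implied by a
#' two-state Markov chain with onset probability
#' `plogis(mu + amplitude * cos(2 * pi * (d - phase) / 365.25))` on day
#' `d` of the calendar year and persistence `p_stay`. The chain is
#' iterated over repeated annual cycles until the prevalence profile
#' converges to its periodic fixed point.
#'
#' @param mu,amplitude,phase,p_stay Chain parameters as in
#'   [cohort_config()].
#' @param n_cycles Number of annual warm-up cycles.
#' @return Numeric vector of length 365: prevalence for each day of year.
#' @export
seasonal_prevalence <- function(mu, amplitude, phase, p_stay,
                                n_cycles = 20) {
  days <- seq_len(365)
  p_on <- plogis(mu + amplitude * cos(2 * pi * (days - phase) / 365.25))
  prev <- rep(p_on[1] / (p_on[1] + 1 - p_stay), 365)
  pi_d <- prev[365]
  for (cycle in seq_len(n_cycles)) {
    for (d in days) {
      pi_d <- (1 - pi_d) * p_on[d] + pi_d * p_stay
      prev[d] <- pi_d
    }
  }
  prev
}
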