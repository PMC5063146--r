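# Synthetic single-fly behavioral datasets: binary light/shade choice
# matrices and continuous thermal-gradient position matrices with the
# statistical structure the downstream estimators assume.

new_behavior_matrix <- function(x, class, fly_ids, immobile = NULL) {
  rownames(x) <- fly_ids
  colnames(x) <- paste0("trial_", seq_len(ncol(x)))
  structure(x, class = c(class, "behavior_matrix"),
            n_trials = ncol(x), immobile = immobile)
}

# Score a vector of per-fly choice probabilities into a 0/1 trial matrix.
score_choices <- function(p, n_trials) {
  matrix(stats::rbinom(length(p) * n_trials, 1L, rep(p, n_trials)),
         nrow = length(p), ncol = n_trials)
}

inject_immobility <- function(m, flies, run_len) {
  imm <- matrix(FALSE, nrow(m), ncol(m))
  for (f in flies) {
    start <- sample(2:(ncol(m) - run_len + 1L), 1L)
    idx <- start:(start + run_len - 1L)
    m[f, idx] <- m[f, start - 1L]
    imm[f, idx] <- TRUE
  }
  list(m = m, immobile = imm)
}

#' Generate a synthetic light/shade choice matrix
#'
#' Each fly receives a light-choice probability `p_i` (drawn from `dist`, or
#' fixed if `dist` is a single number) and its trials are independent
#' Bernoulli(`p_i`) choices (1 = light, 0 = shade).  Missing trials are
#' injected independently per trial; immobility runs -- the artifact the
#' trial filter screens for -- can be injected for chosen flies by repeating
#' the previous choice and flagging the trials in the `immobile` attribute.
#'
#' @param n_flies,n_trials Matrix dimensions (`>= 1`); the phototaxis assay
#'   used 24 trials per fly.
#' @param dist A [pref_dist] or a single fixed probability in \[0, 1\].
#' @param missing_rate Per-trial independent missingness probability in
#'   \[0, 1).
#' @param seed Integer seed; identical seeds give identical matrices.
#' @param immobile_flies Row indices receiving an injected immobility run.
#' @param immobile_run Length of each injected run.
#' @return A `choice_matrix` (flies x trials, entries 0/1/`NA`) with
#'   attributes `n_trials`, `immobile` (logical matrix or `NULL`) and
#'   `true_p` (the generating per-fly probabilities).
#' @examples
#' m <- gen_choice_matrix(50, 24, default_pref_dist(), seed = 1)
#' mean(rowMeans(m, na.rm = TRUE))
#' @export
gen_choice_matrix <- function(n_flies, n_trials = 24L,
                              dist = default_pref_dist(),
                              missing_rate = 0, seed = NULL,
                              immobile_flies = integer(0),
                              immobile_run = 3L) {
  if (n_flies < 1L || n_trials < 1L)
    stop("`n_flies` and `n_trials` must be at least 1", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("`missing_rate` must lie in [0, 1)", call. = FALSE)
  if (is.numeric(dist)) {
    if (length(dist) != 1L || dist < 0 || dist > 1)
      stop("a fixed probability must be a single value in [0, 1]",
           call. = FALSE)
    dist <- if (dist <= 0 || dist >= 1) {
      structure(list(type = "point", at = dist), class = "pref_dist")
    } else pref_point(dist)
  }
  if (!inherits(dist, "pref_dist"))
    stop("`dist` must be a pref_dist or a single probability", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  p <- rpref(n_flies, dist)
  m <- score_choices(p, n_trials)
  imm <- NULL
  if (length(immobile_flies)) {
    inj <- inject_immobility(m, immobile_flies, immobile_run)
    m <- inj$m
    imm <- inj$immobile
  }
  if (missing_rate > 0)
    m[stats::runif(length(m)) < missing_rate] <- NA_integer_
  out <- new_behavior_matrix(m, "choice_matrix",
                             paste0("fly_", seq_len(n_flies)), imm)
  attr(out, "true_p") <- p
  out
}

#' Generate a synthetic thermal-gradient position matrix
#'
#' Per-fly mean positions are Normal(`grand_mean`, `between_sd`); trials are
#' Normal(fly mean, `within_sd`) and finally clipped to the gradient bounds
#' (an arena has walls; clipping is applied last, after missingness, so
#' non-missing values always lie within bounds).  With the study's
#' thermotaxis design, `between_sd = 1.4` C and `within_sd = 3.37` C
#' reproduce the observed ~14.7% between-fly variance fraction.
#'
#' @param n_flies,n_trials Matrix dimensions; the thermotaxis assay used 20
#'   trials per fly.
#' @param grand_mean Population mean position (C).
#' @param between_sd,within_sd Between-fly and within-fly SDs (C), `>= 0`.
#' @param bounds Ordered gradient bounds (C), default `c(18, 30)`.
#' @param missing_rate,seed,immobile_flies,immobile_run As in
#'   [gen_choice_matrix()].
#' @return A `position_matrix` with attributes `n_trials`, `bounds`,
#'   `immobile`, and `true_mean` (generating per-fly means).
#' @export
gen_position_matrix <- function(n_flies, n_trials = 20L, grand_mean = 23.1,
                                between_sd = 1.4, within_sd = 3.37,
                                bounds = c(18, 30), missing_rate = 0,
                                seed = NULL, immobile_flies = integer(0),
                                immobile_run = 3L) {
  if (n_flies < 1L || n_trials < 1L)
    stop("`n_flies` and `n_trials` must be at least 1", call. = FALSE)
  if (between_sd < 0 || within_sd < 0)
    stop("`between_sd` and `within_sd` must be nonnegative", call. = FALSE)
  if (length(bounds) != 2L || bounds[1] >= bounds[2])
    stop("`bounds` must be an ordered pair", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  mu <- stats::rnorm(n_flies, grand_mean, between_sd)
  m <- matrix(stats::rnorm(n_flies * n_trials, rep(mu, n_trials), within_sd),
              nrow = n_flies)
  imm <- NULL
  if (length(immobile_flies)) {
    inj <- inject_immobility(m, immobile_flies, immobile_run)
    m <- inj$m
    imm <- inj$immobile
  }
  if (missing_rate > 0)
    m[stats::runif(length(m)) < missing_rate] <- NA_real_
  m <- pmin(pmax(m, bounds[1]), bounds[2])
  out <- new_behavior_matrix(m, "position_matrix",
                             paste0("fly_", seq_len(n_flies)), imm)
  attr(out, "bounds") <- bounds
  attr(out, "true_mean") <- mu
  out
}

#' Generate a synthetic parent-offspring cross dataset
#'
#' Emulates the selection-cross design used to test heritability of
#' phototactic preference: a source population is scored, sire/dam pairs are
#' taken from the extreme shade- and light-preferring quantiles, and each
#' pair's brood is scored in the same assay.  Progeny preference is
#' `h2 * midparent + (1 - h2) * fresh draw` from `dist`, where the midparent
#' value is the mean of the two parents' measured scores, so the downstream
#' regression estimator is consistent for `h2`.
#'
#' @param h2 True heritability in \[0, 1\].
#' @param n_crosses_per_arm Crosses per selection arm (`shade`, `light`).
#' @param brood_size Progeny scored per cross (`>= 1`).
#' @param dist Preference distribution of the source population.
#' @param selection_quantile Fraction of the scored population treated as an
#'   extreme; must lie in (0, 0.5) and be large enough to supply
#'   `2 * n_crosses_per_arm` parents per arm.
#' @param n_trials Trials per fly in every scoring matrix.
#' @param pop_size Number of flies in the source population.
#' @param seed Integer seed.
#' @return A `cross_dataset`: `parent_scores` (data frame with arm, sire,
#'   dam and midparent scores), `broods` (list of `choice_matrix`), and
#'   `population` (the source `choice_matrix`).
#' @export
gen_cross_dataset <- function(h2, n_crosses_per_arm, brood_size,
                              dist = default_pref_dist(),
                              selection_quantile = 0.1, n_trials = 24L,
                              pop_size = 219L, seed = NULL) {
  if (h2 < 0 || h2 > 1) stop("`h2` must lie in [0, 1]", call. = FALSE)
  if (brood_size < 1L) stop("`brood_size` must be at least 1", call. = FALSE)
  if (selection_quantile <= 0 || selection_quantile >= 0.5)
    stop("`selection_quantile` must lie in (0, 0.5)", call. = FALSE)
  n_extreme <- floor(pop_size * selection_quantile)
  if (n_extreme < 2L * n_crosses_per_arm)
    stop(sprintf(
      "population of %d supplies only %d flies per %.2f-quantile arm; %d needed",
      pop_size, n_extreme, selection_quantile, 2L * n_crosses_per_arm),
      call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  population <- gen_choice_matrix(pop_size, n_trials, dist)
  scores <- rowMeans(population, na.rm = TRUE)
  ord <- order(scores)
  shade_pool <- sample(ord[seq_len(n_extreme)])
  light_pool <- sample(ord[seq(pop_size - n_extreme + 1L, pop_size)])

  parent_rows <- list()
  broods <- list()
  for (arm in c("shade", "light")) {
    pool <- if (arm == "shade") shade_pool else light_pool
    for (i in seq_len(n_crosses_per_arm)) {
      sire <- pool[2L * i - 1L]
      dam <- pool[2L * i]
      mid <- mean(scores[c(sire, dam)])
      p_prog <- h2 * mid + (1 - h2) * rpref(brood_size, dist)
      brood <- new_behavior_matrix(
        score_choices(p_prog, n_trials), "choice_matrix",
        paste0(arm, i, "_prog", seq_len(brood_size)))
      cross_id <- paste0(arm, "_", i)
      parent_rows[[cross_id]] <- data.frame(
        cross = cross_id, arm = arm,
        sire_score = scores[sire], dam_score = scores[dam],
        midparent = mid, stringsAsFactors = FALSE)
      broods[[cross_id]] <- brood
    }
  }
  structure(list(parent_scores = do.call(rbind, c(parent_rows,
                                                  make.row.names = FALSE)),
                 broods = broods, population = population, h2 = h2),
            class = "cross_dataset")
}

#' Read and write behavioral matrices as CSV
#'
#' One row per fly with a mandatory header `fly_id, trial_1..trial_n`;
#' missing trials are empty fields.
#'
#' @param m A `choice_matrix` or `position_matrix`.
#' @param path File path.
#' @return `write_behavior_csv` returns `path` invisibly;
#'   `read_behavior_csv` returns a behavior matrix of the requested type.
#' @export
write_behavior_csv <- function(m, path) {
  stopifnot(inherits(m, "behavior_matrix"))
  df <- data.frame(fly_id = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_behavior_csv
#' @param type `"choice"` (binary) or `"position"` (C).
#' @param bounds Gradient bounds attached to a position matrix.
#' @export
read_behavior_csv <- function(path, type = c("choice", "position"),
                              bounds = c(18, 30)) {
  type <- match.arg(type)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!identical(names(df)[1], "fly_id") ||
      !all(grepl("^trial_", names(df)[-1])))
    stop("expected header `fly_id, trial_1, ...`", call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  if (type == "choice") {
    if (!all(m %in% c(0, 1) | is.na(m)))
      stop("choice entries must be 0, 1 or missing", call. = FALSE)
    out <- new_behavior_matrix(m, "choice_matrix", df$fly_id)
  } else {
    out <- new_behavior_matrix(m, "position_matrix", df$fly_id)
    attr(out, "bounds") <- bounds
  }
  out
}
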