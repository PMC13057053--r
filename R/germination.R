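#' Construct a germination time-course record
#'
#' A germination time-course is the raw substrate of all germination indices:
#' the number of seeds that germinated *for the first time* on each scoring
#' day for one petri dish (one genotype x treatment x replicate).
#'
#' @param genotype_id Genotype identifier.
#' @param treatment Treatment label, one of `"C"` (control), `"D"` (drought),
#'   `"CN"` (control + nano-priming), `"DN"` (drought + nano-priming).
#' @param replicate Positive integer replicate (dish) number.
#' @param daily_counts Integer vector; element `g` is the number of seeds
#'   newly germinated on day `g` (1-based day index, first scoring at 24 h).
#' @param total_seeds Seeds sown per dish (default 20).
#'
#' @return An object of class `"germ_course"`: a list with the validated
#'   fields above.
#' @examples
#' tc <- germ_course("G1", "C", 1, c(5, 10, 5, rep(0, 9)))
#' germination_percentages(tc$daily_counts, tc$total_seeds)
#' @export
germ_course <- function(genotype_id, treatment, replicate, daily_counts,
                        total_seeds = 20L) {
  treatment <- match.arg(treatment, c("C", "D", "CN", "DN"))
  daily_counts <- as.integer(daily_counts)
  if (length(daily_counts) < 1L || anyNA(daily_counts) || any(daily_counts < 0L))
    stop("daily_counts must be a non-empty vector of non-negative integers")
  if (!is.numeric(total_seeds) || total_seeds < 1L)
    stop("total_seeds must be a positive integer")
  if (sum(daily_counts) > total_seeds)
    stop("sum(daily_counts) exceeds total_seeds")
  if (replicate < 1L) stop("replicate must be a positive integer")
  structure(list(genotype_id = as.character(genotype_id),
                 treatment = treatment,
                 replicate = as.integer(replicate),
                 total_seeds = as.integer(total_seeds),
                 daily_counts = daily_counts),
            class = "germ_course")
}

undefined_stat <- function(what, strict, warn = TRUE) {
  if (strict) stop("undefined statistic: ", what, call. = FALSE)
  if (warn) warning("undefined statistic: ", what, "; returning NA", call. = FALSE)
  NA_real_
}

#' Final and initial germination percentage
#'
#' `FG%` is the cumulative germination at the end of the assay expressed as a
#' percentage of seeds sown; `IG%` is the same for the first scoring day only.
#'
#' @param daily_counts Vector of newly-germinated-seed counts per day.
#' @param total_seeds Seeds sown per dish.
#' @return Named list with `fg_pct` and `ig_pct` (percent, 0-100).
#' @examples
#' germination_percentages(c(5, 10, rep(0, 10)), 20)  # FG 75, IG 25
#' @export
germination_percentages <- function(daily_counts, total_seeds = 20L) {
  if (total_seeds <= 0) stop("total_seeds must be positive")
  if (any(daily_counts < 0)) stop("negative daily count")
  list(fg_pct = 100 * sum(daily_counts) / total_seeds,
       ig_pct = 100 * daily_counts[1L] / total_seeds)
}

#' Germination timing indices: MGT, MGR, GP and CVt
#'
#' Mean germination time `MGT = sum(n_g * g) / sum(n_g)` (days, with `g` the
#' 1-based day index); mean germination rate `MGR = 1/MGT` (1/day);
#' germination pace `GP = 100 * N / sum(n_g * g)`, which is identically
#' `100 * MGR`; and the coefficient of variation of germination time
#' `CVt = 100 * s_t / MGT`, where `s_t` is the sample (n-1 denominator)
#' standard deviation of the individual seeds' germination days.
#'
#' @param daily_counts Vector of newly-germinated-seed counts per day.
#' @param strict If `TRUE`, undefined statistics raise an error instead of
#'   returning `NA` with a warning.
#' @return Named list with `mgt` (days), `mgr` (1/days), `gp` (percent) and
#'   `cvt` (percent). With zero germinated seeds all four are undefined; with
#'   a single germinated seed only `cvt` is undefined.
#' @examples
#' germination_timing(c(5, 10, 5))  # MGT 2, MGR 0.5, GP 50
#' @export
germination_timing <- function(daily_counts, strict = FALSE) {
  if (any(daily_counts < 0)) stop("negative daily count")
  n_tot <- sum(daily_counts)
  if (n_tot == 0) {
    na <- undefined_stat("no germinated seeds (MGT/MGR/GP/CVt)", strict)
    return(list(mgt = na, mgr = na, gp = na, cvt = na))
  }
  g <- seq_along(daily_counts)
  mgt <- sum(daily_counts * g) / n_tot
  mgr <- 1 / mgt
  gp <- 100 * mgr   # N / sum(n*g) is algebraically 1/MGT: keep the identity exact
  if (n_tot < 2) {
    cvt <- undefined_stat("CVt with a single germinated seed", strict)
  } else {
    # sample variance of the per-seed germination days, from grouped counts
    s2 <- sum(daily_counts * (g - mgt)^2) / (n_tot - 1)
    cvt <- 100 * sqrt(s2) / mgt
  }
  list(mgt = mgt, mgr = mgr, gp = gp, cvt = cvt)
}

#' Germination uncertainty (U) and synchrony (Z)
#'
#' `U` is the Shannon entropy, in bits, of the distribution of germination
#' events over days: `U = -sum f_i log2 f_i` with `f_i = n_i / sum(n_i)` over
#' days with `n_i > 0` (`0 * log 0` taken as 0). `Z` is the proportion of
#' pairs of germinated seeds that germinated on the same day:
#' `Z = sum C(n_i, 2) / C(N, 2)`. `U = 0` and `Z = 1` both characterise
#' perfectly synchronous germination (all events on one day).
#'
#' @inheritParams germination_timing
#' @return Named list with `u` (bits, >= 0) and `z` (unitless, in \[0, 1\]).
#'   `Z` requires at least two germinated seeds; `U` at least one.
#' @examples
#' germination_information(c(0, 20, 0))  # U 0, Z 1
#' germination_information(c(5, 10, 5))  # Z = 65/190
#' @export
germination_information <- function(daily_counts, strict = FALSE) {
  if (any(daily_counts < 0)) stop("negative daily count")
  n_tot <- sum(daily_counts)
  if (n_tot == 0) {
    u <- undefined_stat("U with no germinated seeds", strict)
  } else {
    f <- daily_counts[daily_counts > 0] / n_tot
    u <- -sum(f * log2(f))
  }
  if (n_tot < 2) {
    z <- undefined_stat("Z with fewer than two germinated seeds", strict)
  } else {
    ni <- daily_counts[daily_counts > 0]
    z <- sum(ni * (ni - 1) / 2) / (n_tot * (n_tot - 1) / 2)
  }
  list(u = u, z = z)
}

#' Seed vigor index
#'
#' `SVI = seedling length x FG%`. By the classical vigor-index convention the
#' seedling length is shoot length + root length; pass `shoot_length` only to
#' use the shoot-only variant.
#'
#' @param shoot_length Shoot length (cm).
#' @param fg_pct Final germination percentage.
#' @param root_length Root length (cm); 0 gives the shoot-only variant.
#' @return SVI (cm x percent).
#' @examples
#' seed_vigor_index(6, 100, 4)  # 1000
#' @export
seed_vigor_index <- function(shoot_length, fg_pct, root_length = 0) {
  if (any(c(shoot_length, fg_pct, root_length) < 0, na.rm = TRUE))
    stop("negative input to seed_vigor_index")
  (shoot_length + root_length) * fg_pct
}

#' Drought-tolerance index and reduction
#'
#' For a trait measured under paired control and drought conditions,
#' `DTI = 100 * drought / control` (percent; may exceed 100 when the trait is
#' larger under drought, as root length sometimes is) and
#' `reduction = control - drought` (trait units).
#'
#' @param control_value Trait value under control conditions.
#' @param drought_value Trait value under drought conditions.
#' @param strict See [germination_timing()].
#' @return Named list with `dti` (percent) and `reduction`. A zero control
#'   value leaves `dti` undefined; the reduction is still returned.
#' @examples
#' stress_indices(4, 3)  # DTI 75, reduction 1
#' @export
stress_indices <- function(control_value, drought_value, strict = FALSE) {
  stopifnot(is.finite(control_value), is.finite(drought_value))
  dti <- if (control_value == 0)
    undefined_stat("DTI with zero control value", strict)
  else 100 * drought_value / control_value
  list(dti = dti, reduction = control_value - drought_value)
}
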