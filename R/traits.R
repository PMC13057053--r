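#' Canonical trait abbreviations
#'
#' The 14 per-treatment traits scored in each of the four treatments, and the
#' 8 paired stress traits (drought-tolerance indices and reductions) computed
#' for the unprimed (D vs C) and nano-primed (DN vs CN) pairs.
#' @keywords internal
PER_TREATMENT_TRAITS <- c("FG", "IG", "GP", "MGT", "MGR", "U", "Z", "CVt",
                          "SVI", "FW", "SL", "RL", "RNo", "SRR")
STRESS_TRAITS <- c("FWDTI", "SLDTI", "RLDTI", "RNoDTI",
                   "RFW", "RSL", "RRL", "RRNo")

#' Default trait-direction map
#'
#' Direction of desirability used by the selection index: `"increase"` means
#' larger values are closer to the ideotype, `"decrease"` the opposite. Seven
#' base traits measure slowness, non-uniformity or drought damage and are
#' marked `"decrease"`: MGT, U, CVt and the four reductions (RFW, RSL, RRL,
#' RRNo). All other traits (including the drought-tolerance indices) are
#' `"increase"`.
#'
#' @param trait_names Character vector of trait column names, e.g.
#'   `"MGT_D"`, `"FWDTI_DN"`. The base trait is the part before the final
#'   `_<treatment>` suffix.
#' @return Named character vector (`"increase"`/`"decrease"`) over
#'   `trait_names`.
#' @examples
#' trait_directions(c("MGT_D", "FG_D", "RFW_DN"))
#' @export
trait_directions <- function(trait_names) {
  decrease <- c("MGT", "U", "CVt", "RFW", "RSL", "RRL", "RRNo")
  base <- sub("_(C|D|CN|DN)$", "", trait_names)
  stats::setNames(ifelse(base %in% decrease, "decrease", "increase"),
                  trait_names)
}

germ_indices_one_dish <- function(counts, total_seeds, strict = FALSE) {
  pc <- germination_percentages(counts, total_seeds)
  tm <- suppressWarnings(germination_timing(counts, strict))
  uz <- suppressWarnings(germination_information(counts, strict))
  c(FG = pc$fg_pct, IG = pc$ig_pct, GP = tm$gp, MGT = tm$mgt, MGR = tm$mgr,
    U = uz$u, Z = uz$z, CVt = tm$cvt)
}

#' Assemble the genotype x trait table
#'
#' Computes the per-dish germination indices from daily counts, joins the
#' seedling measurements, averages replicates within genotype x treatment,
#' and derives the stress traits (DTI and reduction) from the replicate
#' means, pairing drought with control within each priming level (D vs C,
#' DN vs CN). Column names are `<trait>_<treatment>` (e.g. `MGT_D`,
#' `FWDTI_DN`).
#'
#' @param germination Data frame with columns `genotype`, `treatment`,
#'   `replicate`, `total_seeds` and daily count columns `d1`, `d2`, ...
#' @param seedlings Data frame with columns `genotype`, `treatment`,
#'   `replicate`, `fw_g`, `sl_cm`, `rl_cm`, `rno`. Optional; without it only
#'   the count-derived traits are produced.
#' @param svi_length One of `"total"` (shoot + root, the default) or
#'   `"shoot"`: the seedling length used in the vigor index.
#' @param strict Passed to the index functions; see [germination_timing()].
#' @return A data frame of class `"trait_table"`: first column `genotype`,
#'   remaining columns numeric traits, with a `"directions"` attribute naming
#'   each trait column `"increase"` or `"decrease"`.
#' @export
assemble_trait_table <- function(germination, seedlings = NULL,
                                 svi_length = c("total", "shoot"),
                                 strict = FALSE) {
  svi_length <- match.arg(svi_length)
  need <- c("genotype", "treatment", "replicate", "total_seeds")
  if (!all(need %in% names(germination)))
    stop("germination table must have columns ", paste(need, collapse = ", "))
  day_cols <- grep("^d[0-9]+$", names(germination), value = TRUE)
  day_cols <- day_cols[order(as.integer(sub("^d", "", day_cols)))]
  if (length(day_cols) == 0) stop("no daily count columns (d1, d2, ...) found")
  germination$treatment <- as.character(germination$treatment)
  bad <- setdiff(unique(germination$treatment), c("C", "D", "CN", "DN"))
  if (length(bad)) stop("unknown treatment label(s): ", paste(bad, collapse = ", "))

  # per-dish germination indices
  idx <- t(apply(germination, 1, function(row) {
    germ_indices_one_dish(as.numeric(row[day_cols]),
                          as.numeric(row[["total_seeds"]]), strict)
  }))
  dish <- data.frame(genotype = as.character(germination$genotype),
                     treatment = germination$treatment,
                     replicate = germination$replicate,
                     idx, check.names = FALSE)

  if (!is.null(seedlings)) {
    sneed <- c("genotype", "treatment", "replicate", "fw_g", "sl_cm", "rl_cm", "rno")
    if (!all(sneed %in% names(seedlings)))
      stop("seedling table must have columns ", paste(sneed, collapse = ", "))
    seedlings$genotype <- as.character(seedlings$genotype)
    seedlings$treatment <- as.character(seedlings$treatment)
    key <- function(d) paste(d$genotype, d$treatment, d$replicate, sep = "\r")
    m <- match(key(dish), key(seedlings))
    dish$FW <- seedlings$fw_g[m]
    dish$SL <- seedlings$sl_cm[m]
    dish$RL <- seedlings$rl_cm[m]
    dish$RNo <- seedlings$rno[m]
    dish$SRR <- ifelse(dish$RL > 0, dish$SL / dish$RL, NA_real_)
    root <- if (svi_length == "total") dish$RL else 0
    dish$SVI <- (dish$SL + root) * dish$FG
  }

  trait_cols <- intersect(PER_TREATMENT_TRAITS, names(dish))
  # replicate means within genotype x treatment
  agg <- stats::aggregate(dish[trait_cols],
                          by = list(genotype = dish$genotype,
                                    treatment = dish$treatment),
                          FUN = function(x) mean(x, na.rm = FALSE))
  genotypes <- unique(as.character(germination$genotype))
  out <- data.frame(genotype = genotypes, stringsAsFactors = FALSE)
  for (trt in c("C", "D", "CN", "DN")) {
    sub <- agg[agg$treatment == trt, , drop = FALSE]
    if (nrow(sub) == 0) next
    m <- match(genotypes, sub$genotype)
    for (tr in trait_cols)
      out[[paste0(tr, "_", trt)]] <- sub[[tr]][m]
  }

  # stress traits from replicate means: D vs C (unprimed), DN vs CN (primed)
  pairs <- list(D = c("D", "C"), DN = c("DN", "CN"))
  base_map <- c(FWDTI = "FW", SLDTI = "SL", RLDTI = "RL", RNoDTI = "RNo",
                RFW = "FW", RSL = "SL", RRL = "RL", RRNo = "RNo")
  for (suffix in names(pairs)) {
    drt <- pairs[[suffix]][1]; ctl <- pairs[[suffix]][2]
    for (st in STRESS_TRAITS) {
      b <- base_map[[st]]
      dcol <- paste0(b, "_", drt); ccol <- paste0(b, "_", ctl)
      if (!all(c(dcol, ccol) %in% names(out))) {
        if (dcol %in% names(out) || ccol %in% names(out))
          warning("missing treatment partner for ", st, "_", suffix,
                  "; column omitted")
        next
      }
      is_dti <- grepl("DTI$", st)
      val <- if (is_dti) {
        ifelse(out[[ccol]] == 0, NA_real_, 100 * out[[dcol]] / out[[ccol]])
      } else {
        out[[ccol]] - out[[dcol]]
      }
      out[[paste0(st, "_", suffix)]] <- val
    }
  }

  attr(out, "directions") <- trait_directions(setdiff(names(out), "genotype"))
  class(out) <- c("trait_table", "data.frame")
  out
}

#' Extract the numeric trait matrix from a trait table
#' @param traits A `trait_table` (or plain data frame with a `genotype`
#'   column).
#' @return Numeric matrix, genotypes as rownames.
#' @export
trait_matrix <- function(traits) {
  m <- as.matrix(traits[setdiff(names(traits), "genotype")])
  rownames(m) <- traits$genotype
  storage.mode(m) <- "double"
  m
}
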