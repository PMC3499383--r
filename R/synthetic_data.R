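#' Configuration for the synthetic prohormone generator
#'
#' Defines the statistical structure of a simulated prohormone
#' population: sequence lengths typical of neuropeptide precursors,
#' an optional N-terminal signal peptide, a target prevalence of cleaved
#' sites among K/R candidates, and a mixture over the cleavage-motif
#' classes planted at cleaved sites. The defaults emulate the pattern
#' reported for curated mammalian prohormone sets: ~14.6% of candidate
#' sites cleaved, with cleaved sites dominated by xxKR and the
#' overlapping xxRR/RxxR classes plus a minority of monobasic single-R
#' sites.
#'
#' @param n_records Number of prohormone records to simulate.
#' @param length_range Sequence length range in residues (default 70-300).
#' @param signal_range Signal-peptide length range (default 18-30).
#' @param p_signal Probability a record carries a signal peptide
#'   (default 0.9).
#' @param prevalence Target fraction of candidate sites (K/R residues
#'   outside the signal) that are cleaved (default 0.146).
#' @param motif_mix Mixture over planted motif classes
#'   `xxKR`/`xxRR`/`RxxR`/`singleR`; must sum to 1. The default
#'   0.45/0.20/0.15/0.20 yields marginal tag frequencies approximating
#'   the overlapping 71/41/34% pattern seen in curated data.
#' @param background_basic_rate Per-position probability of a K or R in
#'   background (non-planted) sequence, default 0.11 (natural K+R
#'   frequency). Background basics become uncleaved decoy candidates.
#' @param no_decoy_dibasics If `TRUE`, background sequence contains no
#'   K/R at all, so every candidate is either a planted cleaved site or
#'   one of its constrained support residues and no uncleaved candidate
#'   matches the default known-motif rule (oracle mode). Because the
#'   support residues alone then bound prevalence near 1/2, this mode
#'   plants one site per ~30 mature residues and ignores the prevalence
#'   target.
#' @param seed Integer seed; identical configs give byte-identical
#'   populations.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_records = 50L,
                             length_range = c(70L, 300L),
                             signal_range = c(18L, 30L),
                             p_signal = 0.9,
                             prevalence = 0.146,
                             motif_mix = c(xxKR = 0.45, xxRR = 0.20,
                                           RxxR = 0.15, singleR = 0.20),
                             background_basic_rate = 0.11,
                             no_decoy_dibasics = FALSE,
                             seed = 1L) {
  stopifnot(n_records >= 1L,
            length(length_range) == 2L, length_range[1] <= length_range[2],
            length_range[1] >= 40L,
            length(signal_range) == 2L, signal_range[1] <= signal_range[2],
            p_signal >= 0, p_signal <= 1,
            background_basic_rate >= 0, background_basic_rate < 1)
  if (prevalence <= 0 || prevalence >= 1) {
    stop("prevalence must lie strictly between 0 and 1", call. = FALSE)
  }
  if (is.null(names(motif_mix)) ||
      !all(names(motif_mix) %in% c("xxKR", "xxRR", "RxxR", "singleR")) ||
      any(motif_mix < 0) || abs(sum(motif_mix) - 1) > 1e-8) {
    stop("motif_mix must be a non-negative mixture over ",
         "xxKR/xxRR/RxxR/singleR summing to 1", call. = FALSE)
  }
  structure(list(n_records = as.integer(n_records),
                 length_range = as.integer(length_range),
                 signal_range = as.integer(signal_range),
                 p_signal = p_signal, prevalence = prevalence,
                 motif_mix = motif_mix[motif_mix > 0],
                 background_basic_rate = background_basic_rate,
                 no_decoy_dibasics = isTRUE(no_decoy_dibasics),
                 seed = as.integer(seed)),
            class = "generator_config")
}

NONBASIC18 <- setdiff(AA20, c("K", "R"))

bg_sample <- function(n, config) {
  if (config$no_decoy_dibasics || config$background_basic_rate == 0) {
    sample(NONBASIC18, n, replace = TRUE)
  } else {
    rate <- config$background_basic_rate
    probs <- c(rep((1 - rate) / 18, 18), rate / 2, rate / 2)
    sample(c(NONBASIC18, "K", "R"), n, replace = TRUE, prob = probs)
  }
}

# Residues a motif constrains, as offsets upstream of P1 (0 = P1 itself).
# singleR additionally forces P2/P4 to non-basic residues.
plant_writes <- function(motif, chars, p) {
  w <- list(`0` = "R")
  if (motif == "xxKR") w[["1"]] <- "K"
  if (motif == "xxRR") w[["1"]] <- "R"
  if (motif == "RxxR") w[["3"]] <- "R"
  if (motif == "singleR") {
    for (off in c(1L, 3L)) {
      if (chars[p - off] %in% c("K", "R")) {
        w[[as.character(off)]] <- sample(NONBASIC18, 1L)
      }
    }
  }
  w
}

# Minimum spacing between planted P1 positions so that the constrained
# blocks [p-3, p] of different plants never interact, even through the
# P2/P4 lookbacks of a plant's own support residues (which reach back to
# p-6, so adjacent blocks must end before that).
PLANT_SPACING <- 8L

#' Generate a synthetic annotated prohormone population
#'
#' Builds seeded, reproducible [prohormone_record]s: background residues
#' are drawn i.i.d. (K/R at `background_basic_rate`), then cleaved sites
#' are planted by sampling a motif class from `motif_mix` and writing the
#' residues that class constrains (R at P1; K or R at P2; R at P4; for
#' single-R, non-basic residues at P2/P4), marking the P1 position
#' cleaved. Plants are spaced at least 6 residues apart and never placed
#' in the signal peptide. A global adjustment loop adds or removes
#' planted sites until the realised prevalence (cleaved / candidate K-R
#' sites outside the signal) is as close to the target as one site
#' allows.
#'
#' @param config A [generator_config()].
#' @return A list of [prohormone_record]s carrying a `truth` attribute:
#'   a data frame over all candidate sites with columns `record_id`,
#'   `position`, `residue`, `planted` (logical) and `motif` (`NA` for
#'   decoy sites).
#' @export
generate_prohormones <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_records

  sample_range <- function(lo, hi, n) {
    if (lo == hi) rep(lo, n) else sample(lo:hi, n, replace = TRUE)
  }
  lens <- sample_range(config$length_range[1], config$length_range[2], n)
  has_sig <- runif(n) < config$p_signal
  sigs <- ifelse(has_sig,
                 sample_range(config$signal_range[1],
                              config$signal_range[2], n), 0L)
  pop <- lapply(seq_len(n), function(i) {
    list(id = sprintf("syn%03d", i), chars = bg_sample(lens[i], config),
         signal = sigs[i], plants = integer(0), motifs = character(0),
         undo = list())
  })

  count_candidates <- function(rec) {
    idx <- seq_along(rec$chars) > rec$signal
    sum(rec$chars[idx] %in% c("K", "R"))
  }
  C <- sum(vapply(pop, count_candidates, numeric(1)))
  P <- 0L
  target <- config$prevalence

  eligible <- function(rec) {
    lo <- max(rec$signal + 4L, 4L)
    cand <- lo:length(rec$chars)
    if (length(rec$plants) > 0L) {
      near <- outer(cand, rec$plants, function(a, b) abs(a - b)) <
        PLANT_SPACING
      cand <- cand[!apply(near, 1L, any)]
    }
    cand
  }

  add_plant <- function(i) {
    rec <- pop[[i]]
    cand <- eligible(rec)
    if (length(cand) == 0L) return(FALSE)
    p <- if (length(cand) == 1L) cand else sample(cand, 1L)
    motif <- if (length(config$motif_mix) == 1L) {
      names(config$motif_mix)
    } else {
      sample(names(config$motif_mix), 1L, prob = config$motif_mix)
    }
    writes <- plant_writes(motif, rec$chars, p)
    old <- list()
    for (off in names(writes)) {
      pos <- p - as.integer(off)
      old[[off]] <- rec$chars[pos]
      in_mature <- pos > rec$signal
      delta <- (writes[[off]] %in% c("K", "R")) -
        (rec$chars[pos] %in% c("K", "R"))
      if (in_mature) C <<- C + delta
      rec$chars[pos] <- writes[[off]]
    }
    rec$plants <- c(rec$plants, p)
    rec$motifs <- c(rec$motifs, motif)
    rec$undo[[length(rec$plants)]] <- old
    pop[[i]] <<- rec
    P <<- P + 1L
    TRUE
  }

  remove_plant <- function(i, k) {
    rec <- pop[[i]]
    p <- rec$plants[k]
    old <- rec$undo[[k]]
    for (off in names(old)) {
      pos <- p - as.integer(off)
      delta <- (old[[off]] %in% c("K", "R")) -
        (rec$chars[pos] %in% c("K", "R"))
      if (pos > rec$signal) C <<- C + delta
      rec$chars[pos] <- old[[off]]
    }
    rec$plants <- rec$plants[-k]
    rec$motifs <- rec$motifs[-k]
    rec$undo[[k]] <- NULL
    pop[[i]] <<- rec
    P <<- P - 1L
  }

  if (config$no_decoy_dibasics) {
    # Oracle mode: the candidate set consists only of planted P1 residues
    # and their motif support basics, so cleaved/candidate prevalence has
    # a structural floor set by the motif mix (about 1/2). Plant at a
    # fixed density of one site per ~30 mature residues instead of
    # steering toward the prevalence target.
    for (i in seq_len(n)) {
      n_i <- max(1L, round((lens[i] - sigs[i]) / 30))
      for (k in seq_len(n_i)) add_plant(i)
    }
  } else {
    # Grow until the target is reached or overshot by at most one site.
    max_iter <- 100L + 20L * ceiling(target * (C + 1))
    iter <- 0L
    stalled <- 0L
    while (C == 0 || P / C < target) {
      iter <- iter + 1L
      if (iter > max_iter || stalled > 10L * n) {
        stop("infeasible generator config: cannot reach prevalence ",
             target, " (reached ", signif(ifelse(C > 0, P / C, 0), 3),
             " with ", P, " planted sites)", call. = FALSE)
      }
      i <- if (n == 1L) 1L else sample(n, 1L)
      prev_gap <- abs(ifelse(C > 0, P / C, 0) - target)
      if (add_plant(i)) {
        stalled <- 0L
        if (P > 1L && P / C >= target && abs(P / C - target) > prev_gap) {
          # the last addition overshot more than it helped; drop it
          remove_plant(i, length(pop[[i]]$plants))
          break
        }
      } else {
        stalled <- stalled + 1L
      }
    }
  }

  records <- lapply(pop, function(rec) {
    prohormone_record(rec$id, paste(rec$chars, collapse = ""),
                      cleaved_positions = sort(rec$plants),
                      signal_length = if (rec$signal > 0L) rec$signal
                                      else NA_integer_)
  })
  truth <- do.call(rbind, lapply(pop, function(rec) {
    idx <- which(rec$chars %in% c("K", "R"))
    idx <- idx[idx > rec$signal]
    if (length(idx) == 0L) return(NULL)
    ord <- match(idx, rec$plants)
    data.frame(record_id = rec$id, position = idx,
               residue = rec$chars[idx],
               planted = !is.na(ord),
               motif = ifelse(is.na(ord), NA_character_, rec$motifs[ord]),
               stringsAsFactors = FALSE)
  }))
  rownames(truth) <- NULL
  attr(records, "truth") <- truth
  attr(records, "generator_config") <- config
  records
}

#' Confusion counts against the generator's planted truth
#'
#' Compares per-site cleavage calls with the truth table the generator
#' attached to its records, bypassing the annotation round trip (so the
#' I/O layer can be tested independently).
#'
#' @param records Output of [generate_prohormones()] (must carry the
#'   `truth` attribute).
#' @param predictions Data frame with columns `record_id`, `position` and
#'   logical `predicted`; must cover every candidate site in the truth
#'   table.
#' @return A `confusion_counts` object.
#' @export
truth_confusion <- function(records, predictions) {
  truth <- attr(records, "truth")
  if (is.null(truth)) {
    stop("records carry no truth attribute; use generate_prohormones()",
         call. = FALSE)
  }
  stopifnot(is.data.frame(predictions),
            all(c("record_id", "position", "predicted") %in%
                  names(predictions)))
  key_t <- paste(truth$record_id, truth$position)
  key_p <- paste(predictions$record_id, predictions$position)
  idx <- match(key_t, key_p)
  if (anyNA(idx)) {
    stop("predictions do not cover all candidate sites (",
         sum(is.na(idx)), " missing)", call. = FALSE)
  }
  count_confusion(truth$planted, predictions$predicted[idx])
}
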