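# Synthetic-data generators with ground truth: i.i.d. background sequence
# at a chosen AT fraction, motif planting, log-normal expression tables
# with per-category fold effects, and random evidence tables. Every
# generator is a pure function of its parameters and seed.
#
# Defaults encode the study conditions the analysis assumes: 21 promoter
# windows of 4,000 bp at 57.4% AT for sequence sets, and zygotic genes
# down-regulated about 4.3-fold in the mutant (housekeeping unchanged) for
# expression tables.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate i.i.d. background sequences
#'
#' Bases are drawn independently with `P(A) = P(T) = at_fraction / 2` and
#' `P(G) = P(C) = (1 - at_fraction) / 2`, matching the compositional
#' background the enrichment null assumes. Deterministic under `seed`.
#'
#' @param count number of sequences (default 21).
#' @param length length of each sequence in bp (default 4000).
#' @param at_fraction AT fraction in (0, 1), exclusive ends except that
#'   1 and 0 are allowed for degenerate test cases (default 0.574).
#' @param seed integer seed.
#' @return list with `sequences` (named character vector `seq_1`, ...) and
#'   `truth` (list of per-sequence planted-site records, all empty here,
#'   plus the generator parameters).
#' @export
gen_background_sequences <- function(count = 21, length = 4000,
                                     at_fraction = 0.574, seed = 1) {
  if (count < 1 || length < 1)
    stop("count and length must be >= 1", call. = FALSE)
  if (at_fraction < 0 || at_fraction > 1)
    stop("at_fraction must lie in [0, 1]", call. = FALSE)
  p <- c(A = at_fraction / 2, C = (1 - at_fraction) / 2,
         G = (1 - at_fraction) / 2, T = at_fraction / 2)
  seqs <- with_seed(seed, {
    vapply(seq_len(count), function(i)
      paste(sample(names(p), length, replace = TRUE, prob = p),
            collapse = ""),
      character(1))
  })
  names(seqs) <- paste0("seq_", seq_len(count))
  truth <- list(
    planted = stats::setNames(rep(list(integer(0)), count), names(seqs)),
    motif = NULL,
    params = list(count = count, length = length,
                  at_fraction = at_fraction, seed = seed))
  list(sequences = seqs, truth = truth)
}

# sample one concrete realization of a motif: fixed positions as given,
# degenerate positions drawn from the background restricted to the allowed
# set (keeps overall composition near nominal).
realize_motif <- function(motif, p_base) {
  vapply(motif$allowed, function(set) {
    if (length(set) == 1) return(set)
    pr <- p_base[set]
    sample(set, 1, prob = pr / sum(pr))
  }, character(1)) |> paste(collapse = "")
}

#' Plant motif instances into sequences
#'
#' Writes concrete realizations of the motif (degenerate positions sampled
#' from the background composition) at uniformly drawn non-overlapping
#' offsets, and records the planted offsets as ground truth.
#'
#' @param sequences named character vector (e.g. from
#'   [gen_background_sequences()]`$sequences`).
#' @param motif a `consensus_motif`.
#' @param sites_per_sequence single count or per-sequence integer vector.
#' @param seed integer seed.
#' @param at_fraction background composition used to sample degenerate
#'   positions (default 0.574).
#' @return list with `sequences` (modified) and `truth` (per-sequence
#'   sorted planted offsets, 0-based, plus the motif).
#' @export
plant_motifs <- function(sequences, motif, sites_per_sequence, seed = 1,
                         at_fraction = 0.574) {
  validate_sequences(sequences)
  stopifnot(inherits(motif, "consensus_motif"))
  n <- length(sequences)
  k <- rep_len(as.integer(sites_per_sequence), n)
  if (any(k < 0)) stop("sites_per_sequence must be >= 0", call. = FALSE)
  L <- motif$length
  lens <- nchar(sequences)
  if (any(k * L > lens))
    stop("cannot fit ", max(k), " non-overlapping ", L,
         "-bp sites in a ", min(lens), "-bp sequence", call. = FALSE)
  p_base <- c(A = at_fraction / 2, C = (1 - at_fraction) / 2,
              G = (1 - at_fraction) / 2, T = at_fraction / 2)
  planted <- stats::setNames(rep(list(integer(0)), n), names(sequences))
  sequences <- with_seed(seed, {
    out <- sequences
    for (i in seq_len(n)) {
      if (k[i] == 0) next
      avail <- 0:(lens[i] - L)          # candidate 0-based offsets
      chosen <- integer(0)
      for (j in seq_len(k[i])) {
        if (length(avail) == 0)
          stop("could not place ", k[i], " non-overlapping sites in ",
               names(sequences)[i], call. = FALSE)
        o <- if (length(avail) == 1) avail else sample(avail, 1)
        chosen <- c(chosen, o)
        avail <- avail[abs(avail - o) >= L]
      }
      chosen <- sort(chosen)
      s <- out[[i]]
      for (o in chosen) {
        site <- realize_motif(motif, p_base)
        substr(s, o + 1L, o + L) <- site
      }
      out[i] <- s
      planted[[i]] <- chosen
    }
    out
  })
  list(sequences = sequences,
       truth = list(planted = planted, motif = motif,
                    params = list(sites_per_sequence = k, seed = seed,
                                  at_fraction = at_fraction)))
}

#' Generate a synthetic expression table with category effects
#'
#' Wild-type gene means are log-normal; mutant means are the wild-type
#' mean times the category fold effect times a log-normal spread; replicate
#' values multiply the condition mean by log-normal noise. The default
#' effects emulate a mutant in which zygotic genes lose activation (4.3-fold
#' down on average) while maternal and housekeeping genes are unchanged.
#'
#' @param n_per_category named integer vector of gene counts per category
#'   (default: 100 zygotic, 100 maternal, 60 maternal_zygotic,
#'   40 housekeeping, 700 other).
#' @param wt_log_mean,wt_log_sd natural-log mean and sd of wild-type means
#'   (defaults log(500) and 1).
#' @param effect_per_category named vector of mutant/wild-type fold effects
#'   (default: zygotic 1/4.3, others 1).
#' @param effect_log_sd sd of the per-gene log effect spread (default 0.1).
#' @param noise_log_sd sd of the per-replicate log noise (default 0.1).
#' @param replicates replicates per condition (default 3).
#' @param seed integer seed.
#' @return list with `table` (expression data frame: `gene_id`,
#'   `wt_rep*`, `mut_rep*`), `categories` (named vector), and `truth`
#'   (per-gene category and realized fold effect plus parameters).
#' @export
gen_expression <- function(n_per_category = c(zygotic = 100, maternal = 100,
                                              maternal_zygotic = 60,
                                              housekeeping = 40,
                                              other = 700),
                           wt_log_mean = log(500), wt_log_sd = 1,
                           effect_per_category = c(zygotic = 1 / 4.3,
                                                   maternal = 1,
                                                   maternal_zygotic = 1,
                                                   housekeeping = 1,
                                                   other = 1),
                           effect_log_sd = 0.1, noise_log_sd = 0.1,
                           replicates = 3, seed = 1) {
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (effect_log_sd < 0 || noise_log_sd < 0 || wt_log_sd < 0)
    stop("sd parameters must be >= 0", call. = FALSE)
  cats <- names(n_per_category)
  if (is.null(cats) || !all(cats %in% GENE_CATEGORIES))
    stop("n_per_category must be named with categories among: ",
         paste(GENE_CATEGORIES, collapse = ", "), call. = FALSE)
  missing_eff <- setdiff(cats, names(effect_per_category))
  if (length(missing_eff))
    stop("no fold effect given for category: ",
         paste(missing_eff, collapse = ", "), call. = FALSE)
  if (any(effect_per_category <= 0))
    stop("fold effects must be positive", call. = FALSE)
  category <- rep(cats, times = n_per_category)
  n <- length(category)
  gene_id <- sprintf("g%04d", seq_len(n))
  out <- with_seed(seed, {
    wt_mean <- exp(stats::rnorm(n, wt_log_mean, wt_log_sd))
    effect <- unname(effect_per_category[category]) *
      exp(stats::rnorm(n, 0, effect_log_sd))
    mut_mean <- wt_mean * effect
    noise <- function(mu) mu * exp(stats::rnorm(n, 0, noise_log_sd))
    wt <- vapply(seq_len(replicates), function(r) noise(wt_mean),
                 numeric(n))
    mut <- vapply(seq_len(replicates), function(r) noise(mut_mean),
                  numeric(n))
    list(wt = wt, mut = mut, effect = effect)
  })
  table <- data.frame(gene_id = gene_id, stringsAsFactors = FALSE)
  for (r in seq_len(replicates)) table[[paste0("wt_rep", r)]] <- out$wt[, r]
  for (r in seq_len(replicates)) table[[paste0("mut_rep", r)]] <- out$mut[, r]
  list(table = table,
       categories = stats::setNames(category, gene_id),
       truth = list(category = stats::setNames(category, gene_id),
                    effect = stats::setNames(out$effect, gene_id),
                    params = list(n_per_category = n_per_category,
                                  wt_log_mean = wt_log_mean,
                                  wt_log_sd = wt_log_sd,
                                  effect_per_category = effect_per_category,
                                  effect_log_sd = effect_log_sd,
                                  noise_log_sd = noise_log_sd,
                                  replicates = replicates, seed = seed)))
}

#' Generate a random evidence table with known cumulative scores
#'
#' Draws random activator-target evidence records (categories sampled with
#' the given weights; duplicate pairs possible) and returns, alongside the
#' records, cumulative activator scores recomputed directly by the
#' max-per-pair rule as ground truth.
#'
#' @param n_activators,n_genes pool sizes (defaults 8 and 21).
#' @param n_records number of evidence records to draw (default 60).
#' @param category_weights sampling probabilities over the evidence
#'   categories (must sum to 1; default uniform).
#' @param seed integer seed.
#' @return list with `records` (evidence data frame) and `truth`
#'   (named cumulative score vector under the max rule).
#' @export
gen_evidence_table <- function(n_activators = 8, n_genes = 21,
                               n_records = 60,
                               category_weights = NULL, seed = 1) {
  cats <- names(EVIDENCE_WEIGHTS)
  if (is.null(category_weights))
    category_weights <- rep(1 / length(cats), length(cats))
  if (abs(sum(category_weights) - 1) > 1e-9)
    stop("category_weights must sum to 1", call. = FALSE)
  records <- with_seed(seed, {
    data.frame(
      activator = paste0("act_", sample.int(n_activators, n_records,
                                            replace = TRUE)),
      target = paste0("gene_", sample.int(n_genes, n_records,
                                          replace = TRUE)),
      category = sample(cats, n_records, replace = TRUE,
                        prob = category_weights),
      source = paste0("ref_", seq_len(n_records)),
      stringsAsFactors = FALSE)
  })
  # ground truth by direct enumeration: max weight per pair, summed
  w <- EVIDENCE_WEIGHTS[records$category]
  key <- paste(records$activator, records$target)
  pair_max <- tapply(w, key, max)
  pair_act <- sub(" .*$", "", names(pair_max))
  truth <- tapply(as.integer(pair_max), pair_act, sum)
  truth <- stats::setNames(as.integer(truth), names(truth))
  list(records = records, truth = truth)
}
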