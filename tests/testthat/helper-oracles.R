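## Independent oracles and shared fixtures for the test suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

## dynamic-programming Levenshtein distance on symbol vectors,
## independent of the package implementation
dp_levenshtein <- function(x, y) {
  n <- length(x); m <- length(y)
  if (n == 0) return(m)
  if (m == 0) return(n)
  prev <- 0:m
  for (i in 1:n) {
    cur <- c(i, numeric(m))
    for (j in 1:m) {
      cur[j + 1] <- min(prev[j + 1] + 1, cur[j] + 1,
                        prev[j] + (x[i] != y[j]))
    }
    prev <- cur
  }
  prev[m + 1]
}

## direct evaluation of the three printed Yule formulas
yule_direct <- function(a, b, c, d) {
  ad <- a * d; bc <- b * c
  list(Q = (ad - bc) / (ad + bc),
       Y = (sqrt(ad) - sqrt(bc)) / (sqrt(ad) + sqrt(bc)),
       phi = (ad - bc) / sqrt((a + b) * (c + d) * (a + c) * (b + d)))
}

## canonical sort used for building key sets in tests
sort_keys <- function(pos) mutation_key(pos, "A", "G")

## a hand-built annotation: plus- and minus-strand copies of the coding
## sequence ATG TTT TAA on a 60 bp genome
toy_two_gene_annotation <- function() {
  cds <- "ATGTTTTAA"
  genome <- paste0(strrep("A", 10), cds, strrep("C", 11),
                   ltspevo:::revcomp(cds), strrep("G", 21))
  df <- data.frame(gene_id = c("plusG", "minusG"),
                   strand = c("+", "-"),
                   start = c(11L, 31L), end = c(19L, 39L),
                   seq = c(cds, cds), stringsAsFactors = FALSE)
  structure(df, genome_seq = genome, genome_length = nchar(genome),
            class = c("gene_models", "data.frame"))
}

## small, fast simulation for module tests
small_sim <- function(seed, ...) {
  simulate_ltsp(sim_config(
    n_populations = 2L,
    sampling_days = c(11L, 64L, 374L, 1095L, 2191L),
    clones_per_sample = 8L, seed = seed, ...))
}

## neutral-only configuration: no adaptive pool, no planted pairs, no
## mutators -- mutation accumulation is purely the neutral background
neutral_config <- function(seed, n_populations = 3L, ...) {
  sim_config(n_populations = n_populations,
             adaptive_loci = 0L,
             contingent_pairs = data.frame(locus_a = character(0),
                                           locus_b = character(0),
                                           strength = numeric(0)),
             mutator_lineages = stats::setNames(list(), character(0)),
             seed = seed, ...)
}

## the strong-signal recovery fixture: six planted pairs at strength 1,
## high founding frequencies, mild frequency drift
recovery_config <- function(seed) {
  gid <- function(i) sprintf("g%02d", i)
  sim_config(seed = seed,
             contingent_pairs = data.frame(
               locus_a = gid(c(4, 6, 8, 10, 12, 14)),
               locus_b = gid(c(5, 7, 9, 11, 13, 15)),
               strength = 1.0, rate_a = 6e-4, rate_b = 5e-3),
             founding_freqs = c(0.35, 0.32, 0.28),
             freq_sd = 0.15)
}

unordered_ids <- function(a, b) paste(pmin(a, b), pmax(a, b))

## evaluate one end-to-end recovery run against the planted ground truth
eval_recovery <- function(seed) {
  sim <- simulate_ltsp(recovery_config(seed))
  lin <- infer_lineages(sim$calls)
  scr <- contingency_screen(sim$calls, lin,
                            exclude = sim$truth$roles$founder_genes,
                            seed = seed)
  res <- scr$results
  truth_ids <- unordered_ids(sim$truth$pairs$locus_a,
                             sim$truth$pairs$locus_b)
  rel_ids <- unordered_ids(res$locus_a, res$locus_b)[res$reliable]
  dir_ok <- dir_tot <- 0L
  d <- scr$directionality
  if (!is.null(d)) {
    d_ids <- unordered_ids(d$locus_a, d$locus_b)
    for (i in seq_len(nrow(d))) {
      if (!(d_ids[i] %in% truth_ids)) next
      if (!(d$direction[i] %in% c("A_first", "B_first"))) next
      dir_tot <- dir_tot + 1L
      j <- match(d_ids[i], truth_ids)
      called_first <- if (d$direction[i] == "A_first") d$locus_a[i] else
        d$locus_b[i]
      if (called_first == sim$truth$pairs$locus_a[j])
        dir_ok <- dir_ok + 1L
    }
  }
  list(sim = sim, lineages = lin, screen = scr,
       n_lineages = sum(!lin$lineages$is_pseudo),
       n_true = length(truth_ids),
       n_reliable = length(rel_ids),
       n_true_found = sum(truth_ids %in% rel_ids),
       n_false = sum(!(rel_ids %in% truth_ids)),
       dir_ok = dir_ok, dir_tot = dir_tot)
}
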