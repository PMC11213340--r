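## synthetic_data: seeded generator of toy genomes and LTSP-like clone
## samples with planted lineages, mutators, convergent loci and
## contingent loci pairs, plus machine-readable ground truth.

sense_codons <- function() {
  if (!is.null(.pkg_cache$sense)) return(.pkg_cache$sense)
  gc_tab <- Biostrings::GENETIC_CODE
  .pkg_cache$sense <- names(gc_tab)[gc_tab != "*"]
  .pkg_cache$sense
}

#' Generate a toy genome with annotated genes
#'
#' Genes start with ATG, end with a stop codon and contain no internal
#' stops; intergenic spacers of at least 20 bp separate them and provide
#' promoter loci.  Roughly one gene in three is placed on the minus
#' strand.  Gene ids are `g01`, `g02`, ...
#'
#' @param n_genes number of genes (>= 1).
#' @param codons_per_gene codons per gene including start and stop
#'   (>= 2).
#' @param intergenic spacer length between genes (>= 20).
#' @param seed optional RNG seed (the caller's RNG state is restored).
#' @return a `gene_models` data frame (columns `gene_id`, `strand`,
#'   `start`, `end`, `seq`) with the genome sequence and length as
#'   attributes.
#' @export
generate_toy_genome <- function(n_genes = 40L, codons_per_gene = 60L,
                                intergenic = 30L, seed = NULL) {
  if (n_genes < 1L) stop_input("n_genes must be >= 1")
  if (codons_per_gene < 2L) stop_input("codons_per_gene must be >= 2")
  if (intergenic < 20L) stop_input("intergenic spacers must be >= 20 bp")
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    stops <- c("TAA", "TAG", "TGA")
    width <- max(2L, nchar(as.character(n_genes)))
    segs <- character(0)
    rows <- vector("list", n_genes)
    pos <- 1L
    spacer <- function() paste(sample(bases, intergenic, replace = TRUE),
                               collapse = "")
    for (i in seq_len(n_genes)) {
      segs <- c(segs, spacer())
      pos <- pos + intergenic
      cds <- paste(c("ATG",
                     sample(sense_codons(), codons_per_gene - 2L,
                            replace = TRUE),
                     sample(stops, 1L)), collapse = "")
      strand <- if (i %% 3L == 0L) "-" else "+"
      glen <- nchar(cds)
      segs <- c(segs, if (strand == "+") cds else revcomp(cds))
      rows[[i]] <- data.frame(gene_id = sprintf("g%0*d", width, i),
                              strand = strand, start = pos,
                              end = pos + glen - 1L, seq = cds,
                              stringsAsFactors = FALSE)
      pos <- pos + glen
    }
    segs <- c(segs, spacer())
    genome <- paste(segs, collapse = "")
    new_gene_models(do.call(rbind, rows), genome, nchar(genome))
  })
}

#' Write a toy genome as FASTA + GFF3
#'
#' @param genes a `gene_models` data frame with genome attributes.
#' @param fasta,gff output paths.
#' @param seqname reference sequence name (default `"toy"`).
#' @return invisibly, `c(fasta, gff)`.
#' @export
write_genome_files <- function(genes, fasta, gff, seqname = "toy") {
  seq <- Biostrings::DNAStringSet(attr(genes, "genome_seq"))
  names(seq) <- seqname
  Biostrings::writeXStringSet(seq, fasta)
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand)
  gr$type <- "CDS"
  gr$ID <- genes$gene_id
  gr$gene <- genes$gene_id
  gr$phase <- 0L
  rtracklayer::export(gr, gff, format = "gff3")
  invisible(c(fasta, gff))
}

#' Simulation configuration for LTSP-like clone sampling
#'
#' The defaults emulate the sampled design of a five-population LTSP
#' experiment: 12 sampling days spanning six years, ~10 sequenced clones
#' per population and day, three founded lineages per population plus an
#' unassignable remainder, a shared pool of convergently mutated
#' adaptive loci, one mutator lineage with a strongly elevated mutation
#' rate, and planted contingent loci pairs in which mutations at the
#' second locus arise preferentially on the background of mutations at
#' the first.
#'
#' Gene roles on the toy genome are fixed by position: genes 1-2 are the
#' founder ("RNA-polymerase-like") genes carrying the lineage-defining
#' mutations, gene 3 is the mutator (mismatch-repair-like) gene, the
#' next `2 * n_pairs` genes host the planted contingent pairs, and the
#' following `adaptive_loci` genes form the shared adaptive pool.
#'
#' @param n_populations number of populations.
#' @param sampling_days sampling days (12 time points by default).
#' @param clones_per_sample clones sequenced per population and day.
#' @param n_lineages lineages founded per population.
#' @param founding_freqs initial lineage frequencies (must sum to <= 1;
#'   the remainder is the unassignable pseudo fraction).
#' @param freq_sd log-normal step SD of the lineage frequency walk per
#'   sampling interval.
#' @param adaptive_loci size of the shared adaptive locus pool.
#' @param adaptive_rate per-locus mutation gain rate (per lineage per
#'   day).
#' @param neutral_rate neutral mutation rate (per genome per day).
#' @param private_days terminal branch length (days) generating
#'   clone-private mutations.
#' @param mutator_lineages named list, population label -> lineage index
#'   that is a mutator (default: lineage 1 of population 1).
#' @param mutator_fold fold-increase of the mutation rate in mutator
#'   lineages.
#' @param contingent_pairs data frame (`locus_a`, `locus_b`, `strength`,
#'   `rate_a`, `rate_b`) of planted pairs; `strength` in [0, 1] is the
#'   fraction of locus-B acquisition propensity requiring a prior
#'   locus-A mutation in the same lineage background; `rate_a` is the
#'   per-day gain rate of the enabling locus and `rate_b` the per-day
#'   gain rate of the contingent locus once enabled (its baseline rate
#'   is `rate_b * (1 - strength)`).  `NULL` uses four default pairs at
#'   strengths 1, 1, 0.9, 0.9 on the reserved pair genes.
#' @param n_genes,codons_per_gene,intergenic toy genome dimensions.
#' @param seed RNG seed (required for reproducibility; default 1).
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_populations = 5L,
                       sampling_days = c(11L, 22L, 32L, 42L, 64L, 127L,
                                         374L, 730L, 1095L, 1460L, 1816L,
                                         2191L),
                       clones_per_sample = 10L,
                       n_lineages = 3L,
                       founding_freqs = c(0.35, 0.30, 0.25),
                       freq_sd = 0.25,
                       adaptive_loci = 20L,
                       adaptive_rate = 4e-4,
                       neutral_rate = 4e-3,
                       private_days = 50,
                       mutator_lineages = list(`1` = 1L),
                       mutator_fold = 20,
                       contingent_pairs = NULL,
                       n_genes = 40L, codons_per_gene = 60L,
                       intergenic = 30L,
                       seed = 1L) {
  cfg <- list(n_populations = as.integer(n_populations),
              sampling_days = sort(as.integer(sampling_days)),
              clones_per_sample = as.integer(clones_per_sample),
              n_lineages = as.integer(n_lineages),
              founding_freqs = founding_freqs, freq_sd = freq_sd,
              adaptive_loci = as.integer(adaptive_loci),
              adaptive_rate = adaptive_rate, neutral_rate = neutral_rate,
              private_days = private_days,
              mutator_lineages = mutator_lineages,
              mutator_fold = mutator_fold,
              contingent_pairs = contingent_pairs,
              n_genes = as.integer(n_genes),
              codons_per_gene = as.integer(codons_per_gene),
              intergenic = as.integer(intergenic),
              seed = as.integer(seed))
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (cfg$n_lineages != length(cfg$founding_freqs))
    stop_input("founding_freqs must have one entry per lineage")
  if (sum(cfg$founding_freqs) > 1 + 1e-12)
    stop_input("founding frequencies must sum to <= 1")
  if (any(cfg$founding_freqs <= 0))
    stop_input("founding frequencies must be positive")
  if (cfg$n_lineages > cfg$clones_per_sample)
    stop_input("more lineages than clones sampled per time point")
  if (cfg$n_genes < 4L)
    stop_input("the toy genome needs at least 4 genes for the gene roles")
  width <- max(2L, nchar(as.character(cfg$n_genes)))
  gid <- function(i) sprintf("g%0*d", width, i)
  n_pairs <- if (is.null(cfg$contingent_pairs)) 4L else
    nrow(cfg$contingent_pairs)
  reserved <- 3L + 2L * n_pairs + cfg$adaptive_loci
  if (is.null(cfg$contingent_pairs)) {
    if (cfg$n_genes < reserved)
      stop_input("n_genes too small for the default gene roles (need ",
                 reserved, ")")
    cfg$contingent_pairs <- data.frame(
      locus_a = gid(c(4L, 6L, 8L, 10L)),
      locus_b = gid(c(5L, 7L, 9L, 11L)),
      strength = c(1, 1, 0.9, 0.9),
      rate_a = 5e-4, rate_b = 5e-3, stringsAsFactors = FALSE)
  } else {
    cp <- cfg$contingent_pairs
    if (!all(c("locus_a", "locus_b", "strength") %in% names(cp)))
      stop_input("contingent_pairs needs locus_a, locus_b, strength")
    if (is.null(cp$rate_a)) cp$rate_a <- rep(5e-4, nrow(cp))
    if (is.null(cp$rate_b)) cp$rate_b <- rep(5e-3, nrow(cp))
    if (any(cp$strength < 0 | cp$strength > 1))
      stop_input("pair strengths must lie in [0, 1]")
    pl <- c(cp$locus_a, cp$locus_b)
    if (anyDuplicated(pl))
      stop_input("a locus may appear in at most one planted pair")
    cfg$contingent_pairs <- cp
  }
  roles <- list(founder_genes = gid(1:2), mutator_gene = gid(3L))
  pair_genes <- unique(c(cfg$contingent_pairs$locus_a,
                         cfg$contingent_pairs$locus_b))
  pool_start <- 4L
  all_ids <- gid(seq_len(cfg$n_genes))
  free <- setdiff(all_ids[pool_start:cfg$n_genes], pair_genes)
  if (length(free) < cfg$adaptive_loci)
    stop_input("n_genes too small for adaptive pool + pair genes")
  roles$pair_genes <- pair_genes
  roles$adaptive_pool <- free[seq_len(cfg$adaptive_loci)]
  cfg$roles <- roles
  bad <- setdiff(pair_genes, all_ids)
  if (length(bad))
    stop_input("pair loci not on the toy genome: ",
               paste(bad, collapse = ", "))
  structure(cfg, class = "sim_config")
}

## a random nonsynonymous SNP within a gene (genomic coordinates)
.random_nonsyn_snp <- function(gene, genes) {
  g <- genes[genes$gene_id == gene, , drop = FALSE]
  gc_tab <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  for (attempt in 1:50) {
    n <- nchar(g$seq)
    off <- sample.int(n - 3L, 1L) - 1L  # skip the stop codon
    ci <- off %/% 3L; wi <- off %% 3L + 1L
    codon <- substr(g$seq, 3L * ci + 1L, 3L * ci + 3L)
    alt_cds <- sample(setdiff(bases, substr(codon, wi, wi)), 1L)
    new_codon <- codon
    substr(new_codon, wi, wi) <- alt_cds
    if (gc_tab[[new_codon]] == "*" ||
        gc_tab[[new_codon]] == gc_tab[[codon]]) next
    if (g$strand == "+") {
      pos <- g$start + off
      ref <- substr(codon, wi, wi); alt <- alt_cds
    } else {
      pos <- g$end - off
      ref <- .complement(substr(codon, wi, wi)); alt <- .complement(alt_cds)
    }
    return(list(position = pos, ref = ref, alt = alt,
                label = paste0(gene, " ", gc_tab[[codon]], ci + 1L,
                               gc_tab[[new_codon]])))
  }
  stop_input("failed to draw a nonsynonymous SNP in ", gene)
}

## neutral SNPs at uniformly random genome positions, avoiding the
## intervals of `exclude_genes` (the planted-pair genes, whose mutation
## process is modeled explicitly)
.random_neutral_snp <- function(n, genes, exclude_genes = character(0)) {
  genome <- attr(genes, "genome_seq")
  L <- attr(genes, "genome_length")
  pos <- sample.int(L, n, replace = TRUE)
  if (length(exclude_genes) && n > 0) {
    ex <- genes[genes$gene_id %in% exclude_genes, , drop = FALSE]
    in_ex <- function(p) {
      hit <- rep(FALSE, length(p))
      for (j in seq_len(nrow(ex)))
        hit <- hit | (p >= ex$start[j] & p <= ex$end[j])
      hit
    }
    for (attempt in 1:100) {
      bad <- in_ex(pos)
      if (!any(bad)) break
      pos[bad] <- sample.int(L, sum(bad), replace = TRUE)
    }
  }
  ref <- substring(genome, pos, pos)
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1),
    USE.NAMES = FALSE)
  data.frame(position = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

.rexp_or_inf <- function(rate) if (rate <= 0) Inf else stats::rexp(1, rate)

## simulate one lineage trunk: ordered heritable mutation events
.simulate_trunk <- function(cfg, genes, founder_snp, is_mutator,
                            mutator_snp) {
  t_end <- max(cfg$sampling_days)
  fold <- if (is_mutator) cfg$mutator_fold else 1
  ev <- list()
  add <- function(time, snp) {
    ev[[length(ev) + 1L]] <<- data.frame(
      time = time, position = snp$position, ref = snp$ref, alt = snp$alt,
      stringsAsFactors = FALSE)
  }
  add(0, founder_snp)
  if (is_mutator) add(0, mutator_snp)
  ## shared adaptive pool
  for (gene in cfg$roles$adaptive_pool) {
    tt <- .rexp_or_inf(cfg$adaptive_rate * fold)
    if (tt <= t_end) add(tt, .random_nonsyn_snp(gene, genes))
  }
  ## planted contingent pairs: locus-B propensity reduced by (1 - s)
  ## until locus A is acquired
  for (i in seq_len(nrow(cfg$contingent_pairs))) {
    p <- cfg$contingent_pairs[i, ]
    t_a <- .rexp_or_inf(p$rate_a * fold)
    ## piecewise-constant hazard for B: rate_b(1-s) before A, rate_b
    ## after (memoryless residual once A is acquired)
    t_b <- min(.rexp_or_inf(p$rate_b * (1 - p$strength) * fold),
               t_a + .rexp_or_inf(p$rate_b * fold))
    if (t_a <= t_end) add(t_a, .random_nonsyn_snp(p$locus_a, genes))
    if (t_b <= t_end) add(t_b, .random_nonsyn_snp(p$locus_b, genes))
  }
  ## neutral background; the mutator gene and the pair genes are
  ## excluded because their mutation processes are the explicit ones
  ## above (on a desk-scale genome uniform background hits would
  ## otherwise corrupt the planted mutator and contingency structure)
  excl <- c(cfg$roles$mutator_gene, cfg$roles$pair_genes)
  n_neutral <- stats::rpois(1, cfg$neutral_rate * fold * t_end)
  if (n_neutral > 0) {
    snps <- .random_neutral_snp(n_neutral, genes, excl)
    snps$time <- sort(stats::runif(n_neutral, 0, t_end))
    for (j in seq_len(n_neutral))
      add(snps$time[j], snps[j, c("position", "ref", "alt")])
  }
  trunk <- do.call(rbind, ev)
  trunk <- trunk[order(trunk$time), , drop = FALSE]
  trunk[!duplicated(trunk$position), , drop = FALSE]
}

#' Simulate an LTSP-like clone sampling experiment
#'
#' Lineages are founded at day 0 by fixed defining mutations in the
#' founder genes, with frequency trajectories following a renormalized
#' geometric (log-normal step) random walk over the sampling days.  At
#' every sampling day, clones are drawn with replacement from the
#' current lineage frequencies; each clone inherits its lineage trunk's
#' accumulated mutation history (adaptive pool gains, planted
#' contingent-pair gains, neutral background) up to that day, plus
#' clone-private neutral mutations from a terminal branch.  Mutator
#' lineages carry a defining mutation in the mutator gene and accumulate
#' mutations at the configured fold-increase.  Unassignable (pseudo)
#' clones carry only independent neutral mutations and never form
#' heritable sublineages.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `ltsp_sim`: list with `calls` (an
#'   annotated, mutator-flagged [ltsp_calls]), `genes` (toy genome),
#'   `truth` (ground truth: `clones`, `pairs`, `roles`, `histories`,
#'   `founders`, `n_emitted_rows`) and `config`.
#' @export
simulate_ltsp <- function(config) {
  cfg <- if (inherits(config, "sim_config")) config else
    validate_sim_config(config)
  with_seed(cfg$seed, {
    genes <- generate_toy_genome(cfg$n_genes, cfg$codons_per_gene,
                                 cfg$intergenic, seed = NULL)
    ## founder mutation pool: two fixed nonsynonymous SNPs per founder
    ## gene, shared across populations (convergent lineage structure)
    draw_founders <- function() lapply(1:4, function(i) {
      gene <- cfg$roles$founder_genes[(i - 1L) %/% 2L + 1L]
      .random_nonsyn_snp(gene, genes)
    })
    founders <- draw_founders()
    for (attempt in 1:20) {
      keys <- vapply(founders, function(f)
        mutation_key(f$position, f$ref, f$alt), character(1))
      if (!anyDuplicated(keys)) break
      founders <- draw_founders()  # rare position collision: redraw
    }

    days <- cfg$sampling_days
    n_steps <- length(days)
    rows <- list(); truth_clones <- list(); histories <- list()
    for (p in seq_len(cfg$n_populations)) {
      pop <- as.character(p)
      mut_lin <- cfg$mutator_lineages[[pop]] %||% integer(0)
      ## trunks
      trunks <- vector("list", cfg$n_lineages)
      lin_founder <- integer(cfg$n_lineages)
      for (i in seq_len(cfg$n_lineages)) {
        fi <- (p - 1L + i - 1L) %% 4L + 1L
        lin_founder[i] <- fi
        is_mut <- i %in% mut_lin
        mut_snp <- if (is_mut)
          .random_nonsyn_snp(cfg$roles$mutator_gene, genes) else NULL
        trunks[[i]] <- .simulate_trunk(cfg, genes, founders[[fi]],
                                       is_mut, mut_snp)
      }
      ## frequency walk on (lineages + pseudo)
      w <- matrix(0, cfg$n_lineages + 1L, n_steps)
      w0 <- c(cfg$founding_freqs, 1 - sum(cfg$founding_freqs))
      w[, 1] <- w0 / sum(w0)
      for (s in 2:n_steps) {
        step <- w[, s - 1] * exp(stats::rnorm(nrow(w), 0, cfg$freq_sd))
        w[, s] <- step / sum(step)
      }
      for (s in seq_len(n_steps)) {
        d <- days[s]
        counts <- as.vector(stats::rmultinom(1, cfg$clones_per_sample,
                                             w[, s]))
        ci <- 0L
        for (i in seq_len(nrow(w))) {
          for (rep_i in seq_len(counts[i])) {
            ci <- ci + 1L
            clone_id <- sprintf("P%s_D%04d_%02d", pop, d, ci)
            pseudo <- i > cfg$n_lineages
            if (!pseudo) {
              trunk <- trunks[[i]]
              inh <- trunk[trunk$time <= d, , drop = FALSE]
              fold <- if (i %in% mut_lin) cfg$mutator_fold else 1
              n_priv <- stats::rpois(1, cfg$neutral_rate * fold *
                                       min(cfg$private_days, d))
              priv <- if (n_priv > 0)
                .random_neutral_snp(n_priv, genes,
                                    c(cfg$roles$mutator_gene,
                                      cfg$roles$pair_genes)) else NULL
              if (!is.null(priv))
                priv <- priv[!duplicated(priv$position) &
                               !priv$position %in% inh$position, ,
                             drop = FALSE]
              muts <- rbind(inh[, c("position", "ref", "alt")], priv)
              lin_label <- paste0("P", pop, ":L", i)
            } else {
              n_own <- stats::rpois(1, cfg$neutral_rate * d)
              muts <- if (n_own > 0)
                .random_neutral_snp(n_own, genes,
                                     c(cfg$roles$mutator_gene,
                                       cfg$roles$pair_genes))
              else data.frame(position = integer(0), ref = character(0),
                              alt = character(0))
              muts <- muts[!duplicated(muts$position), , drop = FALSE]
              lin_label <- paste0("P", pop, ":pseudo")
            }
            if (nrow(muts))
              rows[[length(rows) + 1L]] <- data.frame(
                clone_id = clone_id, population = pop, day = d,
                position = muts$position, ref = muts$ref, alt = muts$alt,
                class = "SNP", stringsAsFactors = FALSE)
            truth_clones[[length(truth_clones) + 1L]] <- data.frame(
              clone_id = clone_id, population = pop, day = d,
              lineage = lin_label,
              founder_label = if (pseudo) NA_character_ else
                founders[[lin_founder[i]]]$label,
              is_mutator = !pseudo && i %in% mut_lin,
              stringsAsFactors = FALSE)
            histories[[clone_id]] <-
              mutation_key(muts$position, muts$ref, muts$alt)
          }
        }
      }
    }
    mutations <- do.call(rbind, rows)
    truth_cl <- do.call(rbind, truth_clones)
    manifest <- truth_cl[, c("clone_id", "population", "day")]
    calls <- ltsp_calls(mutations, clones = manifest)
    calls <- annotate_mutations(calls, genes)
    calls <- flag_mutators(calls,
                           mutator_genes = cfg$roles$mutator_gene)
    truth <- list(
      clones = truth_cl,
      pairs = data.frame(cfg$contingent_pairs,
                         direction = rep("A_first",
                                         nrow(cfg$contingent_pairs)),
                         stringsAsFactors = FALSE),
      roles = cfg$roles,
      founders = data.frame(
        label = vapply(founders, `[[`, "", "label"),
        key = vapply(founders, function(f)
          mutation_key(f$position, f$ref, f$alt), character(1)),
        stringsAsFactors = FALSE),
      histories = histories,
      n_emitted_rows = nrow(mutations))
    structure(list(calls = calls, genes = genes, truth = truth,
                   config = cfg),
              class = "ltsp_sim")
  })
}

#' @export
print.ltsp_sim <- function(x, ...) {
  cat("Simulated LTSP experiment\n")
  cat("  populations:", x$config$n_populations,
      " lineages/population:", x$config$n_lineages,
      " sampling days:", length(x$config$sampling_days), "\n")
  cat("  clones:", nrow(x$calls$clones),
      " mutation calls:", nrow(x$calls$mutations),
      " planted pairs:", nrow(x$truth$pairs), "\n")
  invisible(x)
}

#' Write simulation ground truth to JSON
#'
#' Lossless serialization of the ground-truth object; [read_ground_truth()]
#' restores it.
#'
#' @param truth the `truth` element of an `ltsp_sim` object.
#' @param path output JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read simulation ground truth from JSON
#' @param path JSON path written by [write_ground_truth()].
#' @return the ground-truth list.
#' @export
read_ground_truth <- function(path) {
  gt <- jsonlite::read_json(path, simplifyVector = TRUE)
  gt$histories <- lapply(gt$histories, function(h)
    if (is.null(h)) character(0) else as.character(unlist(h)))
  gt$roles <- lapply(gt$roles, function(r) as.character(unlist(r)))
  gt
}
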