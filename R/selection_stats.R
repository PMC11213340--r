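## selection_stats: synonymous/nonsynonymous site counting, SNP effect
## classification, dN/dS, chi-square neutrality tests and time-resolved
## nonsynonymous fractions.

.pkg_cache <- new.env(parent = emptyenv())

## expected synonymous site weight per codon under a uniform substitution
## model: each of the 3 possible substitutions at each position carries
## weight 1/3; substitutions to stop codons count as nonsynonymous; stop
## codons themselves are excluded (NA).
codon_syn_sites <- function() {
  if (!is.null(.pkg_cache$codon_syn)) return(.pkg_cache$codon_syn)
  gc_tab <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  syn <- stats::setNames(numeric(length(gc_tab)), names(gc_tab))
  for (cd in names(gc_tab)) {
    if (gc_tab[[cd]] == "*") { syn[[cd]] <- NA_real_; next }
    s <- 0
    for (p in 1:3) {
      for (b in bases) {
        if (substr(cd, p, p) == b) next
        alt <- cd
        substr(alt, p, p) <- b
        if (gc_tab[[alt]] == gc_tab[[cd]]) s <- s + 1 / 3
      }
    }
    syn[[cd]] <- s
  }
  .pkg_cache$codon_syn <- syn
  syn
}

.codons_of <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Count expected synonymous and nonsynonymous sites
#'
#' For each coding position, each of the three possible substitutions
#' contributes 1/3 site-weight to the synonymous or nonsynonymous total
#' according to the standard genetic code (uniform substitution model).
#' The terminal stop codon is excluded from the totals; substitutions
#' that create a stop are counted as nonsynonymous.  Genes containing an
#' internal stop codon are skipped with a warning.
#'
#' @param genes a `gene_models` data frame (see [read_annotation()]).
#' @return data frame with columns `scope` (gene id, plus a final
#'   `"genome"` row with the summed totals), `n_sites`, `s_sites`.
#'   For every gene `n_sites + s_sites` equals the number of counted
#'   coding positions.
#' @export
count_syn_nonsyn_sites <- function(genes) {
  stopifnot(is.data.frame(genes), all(c("gene_id", "seq") %in% names(genes)))
  syn_tab <- codon_syn_sites()
  rows <- vector("list", nrow(genes))
  skipped <- character(0)
  for (i in seq_len(nrow(genes))) {
    codons <- .codons_of(genes$seq[i])
    if (length(codons) && is.na(syn_tab[codons[length(codons)]]))
      codons <- codons[-length(codons)]  # drop the terminal stop codon
    if (any(is.na(syn_tab[codons]))) {
      skipped <- c(skipped, genes$gene_id[i])
      next
    }
    s <- sum(syn_tab[codons])
    rows[[i]] <- data.frame(scope = genes$gene_id[i],
                            n_sites = 3 * length(codons) - s,
                            s_sites = s, stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning("skipping gene(s) with internal stop codon(s): ",
            paste(utils::head(skipped, 5), collapse = ", "), call. = FALSE)
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0L)
    stop_input("no usable coding sequences for site counting")
  out <- rbind(out, data.frame(scope = "genome",
                               n_sites = sum(out$n_sites),
                               s_sites = sum(out$s_sites),
                               stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

## locate genes containing given positions; returns index into `genes`
## rows or NA.  Assumes non-overlapping gene intervals (first match wins
## on the rare overlap).
.gene_index <- function(position, genes) {
  ord <- order(genes$start)
  starts <- genes$start[ord]
  ends <- genes$end[ord]
  idx <- findInterval(position, starts)
  hit <- idx >= 1L & !is.na(position)
  hit[hit] <- position[hit] <= ends[idx[hit]]
  out <- rep(NA_integer_, length(position))
  out[hit] <- ord[idx[hit]]
  out
}

#' Classify the coding effect of SNPs
#'
#' Strand-aware codon lookup: a SNP inside an annotated coding sequence
#' is `synonymous` or `nonsynonymous` (substitutions creating a stop
#' codon are nonsynonymous); positions outside every coding sequence are
#' `noncoding`.  Non-SNP records are classified `indel_or_structural`.
#'
#' @param position genomic position(s), 1-based.
#' @param alt alternative allele(s), single base for SNPs.
#' @param genes a `gene_models` data frame.
#' @param class optional mutation class vector; non-`"SNP"` entries are
#'   returned as `indel_or_structural`.
#' @return character vector of coding effects.
#' @export
classify_snp_effect <- function(position, alt, genes, class = NULL) {
  stopifnot(is.data.frame(genes))
  gl <- attr(genes, "genome_length")
  if (!is.null(gl) && any(position > gl | position < 1, na.rm = TRUE))
    stop_input("position outside the genome (length ", gl, ")")
  gc_tab <- Biostrings::GENETIC_CODE
  n <- length(position)
  out <- rep("noncoding", n)
  is_snp <- if (is.null(class)) rep(TRUE, n) else class == "SNP"
  out[!is_snp] <- "indel_or_structural"
  gi <- .gene_index(position, genes)
  todo <- which(is_snp & !is.na(gi))
  for (i in todo) {
    g <- gi[i]
    seq <- genes$seq[g]
    if (genes$strand[g] == "+") {
      off <- position[i] - genes$start[g]
      base <- toupper(alt[i])
    } else {
      off <- genes$end[g] - position[i]
      base <- .complement(toupper(alt[i]))
    }
    ci <- off %/% 3L
    wi <- off %% 3L + 1L
    codon <- substr(seq, 3L * ci + 1L, 3L * ci + 3L)
    if (nchar(codon) != 3L) next  # partial trailing codon: leave noncoding
    new_codon <- codon
    substr(new_codon, wi, wi) <- base
    out[i] <- if (identical(gc_tab[[codon]], gc_tab[[new_codon]]))
      "synonymous" else "nonsynonymous"
  }
  out
}

#' Annotate mutation calls with locus and coding effect
#'
#' Fills the `locus_id` column via [assign_locus()] (genes and promoter
#' loci) and the `coding_effect` column via [classify_snp_effect()].
#'
#' @param calls an [ltsp_calls] object.
#' @param genes a `gene_models` data frame.
#' @return the updated `ltsp_calls` object.
#' @export
annotate_mutations <- function(calls, genes) {
  stopifnot(inherits(calls, "ltsp_calls"))
  m <- calls$mutations
  lmap <- locus_map(genes)
  m$locus_id <- assign_locus(m$position, lmap)
  m$coding_effect <- classify_snp_effect(m$position, m$alt, genes,
                                         class = m$class)
  calls$mutations <- m
  calls
}

#' Flag mutator clones from mutator-gene mutations
#'
#' A clone is flagged as a mutator when it carries any mutation whose
#' locus is in `mutator_genes` (mismatch-repair genes and the
#' polymerase-proofreading gene by default).
#'
#' @param calls an annotated [ltsp_calls] object (`locus_id` set).
#' @param mutator_genes character vector of gene loci.
#' @return the updated `ltsp_calls` object (`clones$is_mutator` filled).
#' @export
flag_mutators <- function(calls, mutator_genes = DEFAULT_MUTATOR_GENES) {
  stopifnot(inherits(calls, "ltsp_calls"))
  if (all(is.na(calls$mutations$locus_id)) && nrow(calls$mutations))
    stop_input("mutations carry no locus assignment; run annotate_mutations()")
  hit <- calls$mutations$locus_id %in% mutator_genes
  mut_clones <- unique(calls$mutations$clone_id[hit])
  calls$clones$is_mutator <- calls$clones$clone_id %in% mut_clones
  calls
}

#' dN/dS from observed mutation counts and site counts
#'
#' `(n_obs / n_sites) / (s_obs / s_sites)`.  When no synonymous
#' mutations are observed but nonsynonymous ones are, the ratio is
#' infinite (`status = "infinite"`); with no observations at all it is
#' undefined (`status = "undefined"`).
#'
#' @param n_obs,s_obs observed nonsynonymous / synonymous SNP counts.
#' @param sites either the data frame from [count_syn_nonsyn_sites()]
#'   (its `"genome"` row is used) or a numeric vector
#'   `c(n_sites, s_sites)`.
#' @return list with elements `dnds`, `n_obs`, `s_obs`, `n_sites`,
#'   `s_sites`, `status`.
#' @export
compute_dnds <- function(n_obs, s_obs, sites) {
  st <- .site_pair(sites)
  if (any(st <= 0)) stop_input("site counts must be positive")
  if (n_obs < 0 || s_obs < 0) stop_input("observed counts must be >= 0")
  status <- "ok"
  if (s_obs == 0 && n_obs > 0) {
    val <- Inf; status <- "infinite"
  } else if (s_obs == 0 && n_obs == 0) {
    val <- NA_real_; status <- "undefined"
  } else {
    val <- (n_obs / st[["n_sites"]]) / (s_obs / st[["s_sites"]])
  }
  list(dnds = val, n_obs = n_obs, s_obs = s_obs,
       n_sites = st[["n_sites"]], s_sites = st[["s_sites"]],
       status = status)
}

.site_pair <- function(sites) {
  if (is.data.frame(sites)) {
    g <- sites[sites$scope == "genome", , drop = FALSE]
    if (nrow(g) != 1L) stop_input("site table lacks a 'genome' row")
    c(n_sites = g$n_sites, s_sites = g$s_sites)
  } else {
    stopifnot(is.numeric(sites), length(sites) == 2L)
    c(n_sites = sites[[1]], s_sites = sites[[2]])
  }
}

#' Chi-square test of neutrality for mutation counts
#'
#' One-degree-of-freedom goodness-of-fit of the observed
#' (nonsynonymous, synonymous) split against the expected split given by
#' the site counts, normalized to the observed total.
#'
#' @inheritParams compute_dnds
#' @return list with `statistic`, `p_value`, `expected` (length-2).
#' @export
chi_square_neutrality <- function(n_obs, s_obs, sites) {
  st <- .site_pair(sites)
  total <- n_obs + s_obs
  if (total < 1) return(list(statistic = NA_real_, p_value = NA_real_,
                             expected = c(NA_real_, NA_real_)))
  expected <- total * st / sum(st)
  obs <- c(n_obs, s_obs)
  statistic <- sum((obs - expected)^2 / expected)
  list(statistic = statistic,
       p_value = stats::pchisq(statistic, df = 1, lower.tail = FALSE),
       expected = unname(expected))
}

## unique mutation events among non-mutator clones: the same mutation key
## within one population counts once (shared by ancestry); the same key in
## different populations counts per population (independent occurrences).
unique_nonmutator_events <- function(calls, snp_only = FALSE) {
  cl <- calls$clones
  if (all(is.na(cl$is_mutator)))
    cl$is_mutator <- FALSE
  keep_clones <- cl$clone_id[!cl$is_mutator]
  m <- calls$mutations[calls$mutations$clone_id %in% keep_clones, ,
                       drop = FALSE]
  if (snp_only) m <- m[m$class == "SNP", , drop = FALSE]
  if (nrow(m) == 0L) return(m)
  ## first-observation day per (population, key)
  first_day <- stats::aggregate(day ~ population + key, data = m, FUN = min)
  meta <- m[!duplicated(m[, c("population", "key")]),
            setdiff(names(m), c("clone_id", "day")), drop = FALSE]
  merge(meta, first_day, by = c("population", "key"))
}

#' Overall and per-time-point dN/dS table
#'
#' Counts unique mutation events in non-mutator clones (a mutation
#' shared by ancestry within a population counts once, dated by the
#' earliest sampling day at which it is observed) and computes dN/dS and
#' the chi-square neutrality test, overall or per first-observation day.
#'
#' @param calls an annotated [ltsp_calls] object with mutator flags set.
#' @param sites site counts (see [compute_dnds()]).
#' @param by `"overall"` or `"day"`.
#' @return data frame with columns `scope`, `n_obs`, `s_obs`, `n_sites`,
#'   `s_sites`, `dnds`, `chi2`, `p`.
#' @export
dnds_table <- function(calls, sites, by = c("overall", "day")) {
  by <- match.arg(by)
  ev <- unique_nonmutator_events(calls, snp_only = TRUE)
  ev <- ev[ev$coding_effect %in% c("synonymous", "nonsynonymous"), ,
           drop = FALSE]
  groups <- if (by == "overall") list(overall = ev) else
    split(ev, ev$day)
  st <- .site_pair(sites)
  rows <- lapply(names(groups), function(g) {
    e <- groups[[g]]
    n_obs <- sum(e$coding_effect == "nonsynonymous")
    s_obs <- sum(e$coding_effect == "synonymous")
    d <- compute_dnds(n_obs, s_obs, st)
    ch <- chi_square_neutrality(n_obs, s_obs, st)
    data.frame(scope = g, n_obs = n_obs, s_obs = s_obs,
               n_sites = st[["n_sites"]], s_sites = st[["s_sites"]],
               dnds = d$dnds, chi2 = ch$statistic, p = ch$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-time-point fraction of nonsynonymous mutations
#'
#' Each unique mutation event (non-mutator clones) is assigned to the
#' sampling day at which it is first observed; per day the fraction
#' `n_obs / (n_obs + s_obs)` is computed, together with the neutral
#' expectation `n_sites / (n_sites + s_sites)` (a property of the genome
#' only).  Days with no classifiable mutations are emitted with an `NA`
#' fraction.
#'
#' @inheritParams dnds_table
#' @return data frame with columns `day`, `n_obs`, `s_obs`, `fraction`,
#'   `neutral_expectation`.
#' @export
nonsyn_fraction_by_timepoint <- function(calls, sites) {
  st <- .site_pair(sites)
  neutral <- st[["n_sites"]] / sum(st)
  ev <- unique_nonmutator_events(calls, snp_only = TRUE)
  ev <- ev[ev$coding_effect %in% c("synonymous", "nonsynonymous"), ,
           drop = FALSE]
  days <- sort(unique(calls$clones$day))
  rows <- lapply(days, function(d) {
    e <- ev[ev$day == d, , drop = FALSE]
    n_obs <- sum(e$coding_effect == "nonsynonymous")
    s_obs <- sum(e$coding_effect == "synonymous")
    data.frame(day = d, n_obs = n_obs, s_obs = s_obs,
               fraction = if (n_obs + s_obs > 0)
                 n_obs / (n_obs + s_obs) else NA_real_,
               neutral_expectation = neutral)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
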