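test_that("site counting matches full codon enumeration", {
  ## independent oracle: enumerate all 9 substitutions per codon
  enum_syn <- function(codon) {
    gc_tab <- Biostrings::GENETIC_CODE
    s <- 0
    for (p in 1:3) for (b in c("A", "C", "G", "T")) {
      if (substr(codon, p, p) == b) next
      alt <- codon; substr(alt, p, p) <- b
      if (gc_tab[[alt]] == gc_tab[[codon]]) s <- s + 1 / 3
    }
    s
  }
  mk_gene <- function(cds) {
    structure(data.frame(gene_id = "g", strand = "+", start = 1,
                         end = nchar(cds), seq = cds,
                         stringsAsFactors = FALSE),
              class = c("gene_models", "data.frame"))
  }
  ## ATG: no synonymous substitution exists
  st <- count_syn_nonsyn_sites(mk_gene("ATGTAA"))
  expect_equal(st$s_sites[st$scope == "g"], 0)
  expect_equal(st$n_sites[st$scope == "g"], 3)
  ## TTT: only TTT->TTC is synonymous
  st <- count_syn_nonsyn_sites(mk_gene("ATGTTTTAA"))
  expect_equal(st$s_sites[st$scope == "g"], enum_syn("ATG") + enum_syn("TTT"))
  expect_equal(st$s_sites[st$scope == "g"], 1 / 3)
  expect_equal(st$n_sites[st$scope == "g"], 6 - 1 / 3)
  ## conservation + oracle agreement on random genes
  genes <- generate_toy_genome(n_genes = 8, codons_per_gene = 20, seed = 5)
  st <- count_syn_nonsyn_sites(genes)
  per_gene <- st[st$scope != "genome", ]
  expect_equal(per_gene$n_sites + per_gene$s_sites,
               rep(3 * 19, 8))  # stop codon excluded
  for (i in sample(nrow(genes), 3)) {
    codons <- substring(genes$seq[i], seq(1, nchar(genes$seq[i]), 3),
                        seq(3, nchar(genes$seq[i]), 3))
    codons <- codons[-length(codons)]
    expect_equal(per_gene$s_sites[per_gene$scope == genes$gene_id[i]],
                 sum(vapply(codons, enum_syn, numeric(1))))
  }
  expect_equal(st$n_sites[st$scope == "genome"], sum(per_gene$n_sites))
})

test_that("genes with internal stop codons are skipped with a warning", {
  bad <- structure(data.frame(gene_id = c("ok", "bad"), strand = "+",
                              start = c(1, 100), end = c(9, 108),
                              seq = c("ATGGCTTAA", "ATGTAATAA"),
                              stringsAsFactors = FALSE),
                   class = c("gene_models", "data.frame"))
  expect_warning(st <- count_syn_nonsyn_sites(bad), "internal stop")
  expect_setequal(st$scope, c("ok", "genome"))
})

test_that("SNP effects classify strand-aware, with noncoding fallback", {
  genes <- toy_two_gene_annotation()
  ## plus gene ATG TTT TAA at 11..19: third position of TTT is pos 16
  expect_equal(classify_snp_effect(16, "C", genes), "synonymous")
  expect_equal(classify_snp_effect(16, "A", genes), "nonsynonymous")
  ## minus gene at 31..39 carries the same CDS on the reverse strand:
  ## CDS offset 5 (third position of TTT) sits at genomic 39 - 5 = 34,
  ## and the synonymous T->C change reads G->A on the plus strand
  expect_equal(classify_snp_effect(34, "G", genes), "synonymous")
  expect_equal(classify_snp_effect(34, "C", genes), "nonsynonymous")
  ## intergenic position
  expect_equal(classify_snp_effect(5, "G", genes), "noncoding")
  ## substitutions creating a stop codon are nonsynonymous:
  ## ATG TAC TAA with TAC -> TAA at the third codon position
  stop_gene <- structure(data.frame(gene_id = "s", strand = "+",
                                    start = 1, end = 9,
                                    seq = "ATGTACTAA"),
                         genome_length = 9,
                         class = c("gene_models", "data.frame"))
  expect_equal(classify_snp_effect(6, "A", stop_gene), "nonsynonymous")
  ## outside the genome
  expect_error(classify_snp_effect(1000, "A", genes), "outside")
  ## non-SNP records pass through as indel_or_structural
  expect_equal(classify_snp_effect(16, "C", genes, class = "small_indel"),
               "indel_or_structural")
})

test_that("effect classification is invariant to the stored strand", {
  set.seed(42)
  for (rep_i in 1:5) {
    cds <- paste(c("ATG", sample(setdiff(names(Biostrings::GENETIC_CODE),
                                         c("TAA", "TAG", "TGA")), 6,
                                 replace = TRUE), "TAA"),
                 collapse = "")
    genome_p <- paste0(strrep("A", 20), cds, strrep("A", 20))
    genome_m <- paste0(strrep("A", 20), ltspevo:::revcomp(cds),
                       strrep("A", 20))
    gp <- structure(data.frame(gene_id = "g", strand = "+", start = 21,
                               end = 20 + nchar(cds), seq = cds),
                    genome_length = nchar(genome_p),
                    class = c("gene_models", "data.frame"))
    gm <- structure(data.frame(gene_id = "g", strand = "-", start = 21,
                               end = 20 + nchar(cds), seq = cds),
                    genome_length = nchar(genome_m),
                    class = c("gene_models", "data.frame"))
    for (off in sample(0:(nchar(cds) - 4), 5)) {
      base <- sample(c("A", "C", "G", "T"), 1)
      ## the CDS-relative substitution (off, base) maps to different
      ## genomic coordinates on the two strands but must classify alike
      eff_p <- classify_snp_effect(21 + off, base, gp)
      eff_m <- classify_snp_effect(20 + nchar(cds) - off,
                                   ltspevo:::.complement(base), gm)
      expect_equal(eff_p, eff_m)
    }
  }
})

test_that("dN/dS returns the ratio of rates with flags for degenerate counts", {
  sites <- c(8, 2)
  expect_equal(compute_dnds(0, 5, sites)$dnds, 0)
  ## observed proportions equal to site proportions give exactly 1
  expect_equal(compute_dnds(8, 2, sites)$dnds, 1)
  expect_equal(compute_dnds(16, 4, sites)$dnds, 1)
  inf_case <- compute_dnds(3, 0, sites)
  expect_equal(inf_case$status, "infinite")
  expect_true(is.infinite(inf_case$dnds))
  undef <- compute_dnds(0, 0, sites)
  expect_equal(undef$status, "undefined")
  expect_error(compute_dnds(1, 1, c(0, 2)), "positive")
})

test_that("chi-square neutrality matches the hand-computed 2-cell statistic", {
  ## 3:1 expected split, (30, 0) observed: (30-22.5)^2/22.5 + 7.5 = 10
  res <- chi_square_neutrality(30, 0, c(3, 1))
  expect_equal(res$statistic, 10)
  expect_equal(res$expected, c(22.5, 7.5))
  ## doubling the observations doubles the statistic in the 2-cell case
  expect_equal(chi_square_neutrality(60, 0, c(3, 1))$statistic, 20)
  ## observed at expectation: statistic 0, p = 1
  at_exp <- chi_square_neutrality(75, 25, c(3, 1))
  expect_equal(at_exp$statistic, 0)
  expect_equal(at_exp$p_value, 1)
  ## cross-check statistic and p against stats::chisq.test
  ct <- suppressWarnings(stats::chisq.test(c(30, 0), p = c(3, 1) / 4))
  expect_equal(res$statistic, unname(ct$statistic))
  expect_equal(res$p_value, ct$p.value)
})

test_that("per-day nonsynonymous fractions use first-observation dating", {
  mutations <- data.frame(
    clone_id = c("c1", "c1", "c1", "c1", "c2", "c3"),
    population = "1",
    day = c(11L, 11L, 11L, 11L, 22L, 22L),
    position = c(1:4, 1L, 5L),
    ref = "A", alt = "G", class = "SNP",
    coding_effect = c("nonsynonymous", "nonsynonymous", "nonsynonymous",
                      "synonymous", "nonsynonymous", "synonymous"))
  calls <- ltsp_calls(mutations)
  out <- nonsyn_fraction_by_timepoint(calls, c(3, 1))
  ## day 11: 3 nonsyn, 1 syn
  expect_equal(out$fraction[out$day == 11], 0.75)
  ## position 1 re-observed at day 22 dates to day 11; only position 5
  ## (synonymous) is new at day 22
  expect_equal(out$n_obs[out$day == 22], 0)
  expect_equal(out$fraction[out$day == 22], 0)
  ## the neutral line depends only on the genome
  expect_equal(unique(out$neutral_expectation), 0.75)
})
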