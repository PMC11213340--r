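## hand-built unit rosters for table construction and directionality
units_fixture <- function(clone_loci, units) {
  list(units = units, clone_loci = clone_loci)
}

test_that("pair tables count units per cell, multi-counting allowed", {
  ## four units: both / A-only / B-only / neither
  su <- units_fixture(
    clone_loci = list(x1 = c("A", "B"), x2 = "A", x3 = "B",
                      x4 = character(0)),
    units = list(u1 = "x1", u2 = "x2", u3 = "x3", u4 = "x4"))
  expect_equal(build_pair_table("A", "B", su),
               c(a = 1L, b = 1L, c = 1L, d = 1L))
  ## one unit holding both a double and an A-only clone counts in a and b
  su2 <- units_fixture(
    clone_loci = list(y1 = c("A", "B"), y2 = "A"),
    units = list(u1 = c("y1", "y2")))
  expect_equal(build_pair_table("A", "B", su2),
               c(a = 1L, b = 1L, c = 0L, d = 0L))
  ## a pair mutated nowhere: d equals the unit count
  expect_equal(build_pair_table("P", "Q", su),
               c(a = 0L, b = 0L, c = 0L, d = 4L))
  expect_error(build_pair_table("A", "B", units_fixture(list(), list())),
               "empty unit roster")
})

test_that("Yule coefficients match their printed closed forms", {
  expect_equal(yule_coefficients(c(a = 5, b = 0, c = 0, d = 15))$Q, 1)
  expect_equal(yule_coefficients(c(a = 5, b = 0, c = 0, d = 15))$Y, 1)
  ind <- yule_coefficients(c(a = 2, b = 2, c = 2, d = 2))
  expect_equal(ind$Q, 0); expect_equal(ind$Y, 0); expect_equal(ind$phi, 0)
  ex <- yule_coefficients(c(a = 6, b = 1, c = 2, d = 11))
  expect_equal(ex$Q, 64 / 68)
  expect_equal(ex$Y, (sqrt(66) - sqrt(2)) / (sqrt(66) + sqrt(2)))
  expect_equal(ex$phi, 64 / sqrt(7 * 13 * 8 * 12))
  ## undefined denominators flag as NA rather than erroring
  degenerate <- yule_coefficients(c(a = 3, b = 0, c = 0, d = 0))
  expect_true(is.na(degenerate$Q))
})

test_that("association tests are one-sided with BH correction", {
  ind <- test_association(yule_coefficients(c(a = 2, b = 2, c = 2, d = 2)))
  expect_equal(ind$p_Q, 0.5)
  expect_equal(ind$p_Y, 0.5)
  expect_equal(ind$p_phi, 0.5)
  ## negative association gives p > 0.5
  neg <- test_association(yule_coefficients(c(a = 1, b = 5, c = 5, d = 1)))
  expect_gt(neg$p_Q, 0.5)
  ## significance sets are nested across alpha
  set.seed(4)
  tabs <- data.frame(a = rpois(50, 4), b = rpois(50, 4),
                     c = rpois(50, 4), d = rpois(50, 4))
  r1 <- test_association(yule_coefficients(tabs), alpha = 0.01)
  r5 <- test_association(yule_coefficients(tabs), alpha = 0.05)
  expect_true(all(which(r1$sig_phi) %in% which(r5$sig_phi)))
  expect_true(all(which(r1$sig_Q) %in% which(r5$sig_Q)))
})

test_that("threshold selection maximizes the functional fraction", {
  res <- data.frame(locus_a = letters[1:5], locus_b = LETTERS[1:5],
                    Q = c(0.9, 0.85, 0.8, 0.6, 0.5),
                    Y = c(0.7, 0.65, 0.5, 0.3, 0.2),
                    sig_Q = TRUE, sig_Y = TRUE)
  fun <- functional_pair_table(letters[1:3], LETTERS[1:3])
  sel <- select_thresholds(res, fun)
  expect_equal(sel$Q, 0.8)
  expect_equal(sel$Y, 0.5)
  ## all pairs functional: every cutoff scores 1, the lowest is returned
  fun_all <- functional_pair_table(letters[1:5], LETTERS[1:5])
  sel_all <- select_thresholds(res, fun_all)
  expect_equal(sel_all$Q, 0.5)
  ## empty table: warning and NULL (significance-only mode)
  expect_warning(sel_none <- select_thresholds(res, NULL), "skipped")
  expect_null(sel_none)
})

test_that("reliability requires all three coefficient criteria", {
  res <- data.frame(locus_a = c("a", "b", "c"), locus_b = c("x", "y", "z"),
                    Q = c(0.9, 0.9, 0.9), Y = c(0.6, 0.4, 0.6),
                    phi = c(0.5, 0.5, 0.5),
                    sig_phi = c(TRUE, TRUE, FALSE))
  out <- consensus_reliable_pairs(res, q_cutoff = 0.8, y_cutoff = 0.5)
  expect_equal(out$reliable, c(TRUE, FALSE, FALSE))
})

test_that("functional enrichment randomization behaves at the extremes", {
  loci <- letters[1:6]
  pairs <- data.frame(locus_a = c("a", "b"), locus_b = c("c", "d"))
  all_pairs <- t(combn(loci, 2))
  fun_all <- functional_pair_table(all_pairs[, 1], all_pairs[, 2])
  res_all <- functional_enrichment(pairs, loci, fun_all, n_rand = 100,
                                   seed = 1)
  expect_equal(res_all$observed_fraction, 1)
  expect_equal(res_all$p_value, 1)
  res_none <- functional_enrichment(pairs, loci, NULL, n_rand = 100,
                                    seed = 1)
  expect_equal(res_none$observed_fraction, 0)
  expect_equal(res_none$p_value, 1)
  expect_error(functional_enrichment(
    data.frame(locus_a = letters[1:4], locus_b = LETTERS[1:4]),
    c("a", "b"), fun_all, n_rand = 10), "fewer possible pairs")
  ## an enriched observed set yields a small smoothed p-value
  fun_obs <- functional_pair_table(c("a", "b"), c("c", "d"))
  res_enr <- functional_enrichment(pairs, loci, fun_obs, n_rand = 1000,
                                   seed = 2)
  expect_equal(res_enr$observed_fraction, 1)
  expect_lte(res_enr$p_value, 0.05)
})

test_that("directionality follows ancestor chains and combines across units", {
  edges <- data.frame(
    population = "1",
    clone_id = c("r1", "d1", "r2", "d2", "r3", "d3"),
    parent_id = c(NA, "r1", NA, "r2", NA, "r3"),
    distance = 1L, day = c(11L, 22L), parent_day = NA_integer_)
  ## A acquired before B in all three units
  su <- units_fixture(
    clone_loci = list(r1 = "A", d1 = c("A", "B"),
                      r2 = "A", d2 = c("A", "B"),
                      r3 = "A", d3 = c("A", "B")),
    units = list(u1 = c("r1", "d1"), u2 = c("r2", "d2"),
                 u3 = c("r3", "d3")))
  pairs <- data.frame(locus_a = "A", locus_b = "B")
  out <- infer_directionality(pairs, su, edges)
  expect_equal(out$direction, "A_first")
  expect_equal(out$n_informative_units, 3L)
  ## swapped pair orientation flips the call
  out_sw <- infer_directionality(data.frame(locus_a = "B", locus_b = "A"),
                                 su, edges)
  expect_equal(out_sw$direction, "B_first")
  ## co-acquired on the same edge in every unit
  su_tog <- units_fixture(
    clone_loci = list(r1 = character(0), d1 = c("A", "B"),
                      r2 = character(0), d2 = c("A", "B"),
                      r3 = character(0), d3 = c("A", "B")),
    units = su$units)
  expect_equal(infer_directionality(pairs, su_tog, edges)$direction,
               "always_together")
  ## units disagreeing on which came first are ambiguous
  su_mix <- units_fixture(
    clone_loci = list(r1 = "A", d1 = c("A", "B"),
                      r2 = "B", d2 = c("A", "B"),
                      r3 = "A", d3 = c("A", "B")),
    units = su$units)
  expect_equal(infer_directionality(pairs, su_mix, edges)$direction,
               "ambiguous")
  ## no informative unit at all
  expect_equal(infer_directionality(data.frame(locus_a = "P",
                                               locus_b = "Q"),
                                    su, edges)$direction, "n/a")
})

test_that("candidate pairs respect convergence, co-mutation and exclusions", {
  sim <- simulate_ltsp(recovery_config(2))
  lin <- infer_lineages(sim$calls)
  founder_genes <- sim$truth$roles$founder_genes
  pairs <- enumerate_candidate_pairs(sim$calls, lin,
                                     exclude = founder_genes)
  expect_true(all(pairs$n_co_units >= 2))
  expect_false(any(pairs$locus_a %in% founder_genes |
                     pairs$locus_b %in% founder_genes))
  ## planted pairs present in multiple lineages are candidates
  truth_ids <- unordered_ids(sim$truth$pairs$locus_a,
                             sim$truth$pairs$locus_b)
  cand_ids <- unordered_ids(pairs$locus_a, pairs$locus_b)
  expect_gt(mean(truth_ids %in% cand_ids), 0.8)
})

test_that("mutator units and clones are excluded from the screen", {
  sim <- simulate_ltsp(recovery_config(1))
  lin <- infer_lineages(sim$calls)
  su <- screen_units(sim$calls, lin)
  mut_lin <- lin$lineages$lineage_id[lin$lineages$is_mutator]
  expect_true(length(mut_lin) >= 1)
  expect_false(any(mut_lin %in% names(su$units)))
  mut_clones <- sim$calls$clones$clone_id[sim$calls$clones$is_mutator]
  expect_false(any(mut_clones %in% unlist(su$units)))
})

test_that("locus-defining-mutation association flags restricted loci", {
  ## four populations, two lineages each, founded by shared mutations
  ## F1/F2; locus X is mutated only on the F1 background
  genes <- generate_toy_genome(n_genes = 6, codons_per_gene = 10, seed = 2)
  f1 <- genes$start[1] + 4L   # inside gene 1 (founder gene)
  f2 <- genes$start[1] + 7L
  x_gene <- genes$gene_id[3]
  rows <- list(); n <- 0
  for (pop in as.character(1:4)) {
    for (lin_i in 1:2) {
      fpos <- if (lin_i == 1) f1 else f2
      for (day in c(11L, 22L)) {
        for (k in 1:3) {
          n <- n + 1
          id <- sprintf("c%03d", n)
          pos <- fpos
          if (lin_i == 1) pos <- c(pos, genes$start[3] + 3L + k)
          rows[[n]] <- data.frame(clone_id = id, population = pop,
                                  day = day, position = pos, ref = "A",
                                  alt = "G", class = "SNP")
        }
      }
    }
  }
  calls <- ltsp_calls(do.call(rbind, rows))
  calls <- annotate_mutations(calls, genes)
  calls <- flag_mutators(calls, mutator_genes = character(0))
  lin <- infer_lineages(calls)
  expect_equal(sum(!lin$lineages$is_pseudo), 8L)
  res <- rnapc_locus_association(calls, lin,
                                 founder_genes = genes$gene_id[1])
  hit <- res[res$locus == x_gene, ]
  expect_equal(nrow(hit), 2L)  # against both defining mutations
  f1_key <- mutation_key(f1, "A", "G")
  row_f1 <- hit[hit$defining_mutation == f1_key, ]
  expect_equal(unname(unlist(row_f1[, c("a", "b", "c", "d")])),
               c(4L, 0L, 0L, 4L))
  expect_equal(row_f1$Q, 1)
  expect_true(row_f1$sig_phi)
  ## the other defining mutation shows perfect negative association
  row_f2 <- hit[hit$defining_mutation != f1_key, ]
  expect_equal(row_f2$Q, -1)
  expect_false(row_f2$sig_phi)
})

test_that("merged gene groups act as one entity in the association", {
  su_genes <- generate_toy_genome(n_genes = 6, codons_per_gene = 10,
                                  seed = 2)
  rows <- list(); n <- 0
  for (pop in as.character(1:3)) {
    for (lin_i in 1:2) {
      fpos <- su_genes$start[1] + if (lin_i == 1) 4L else 7L
      for (day in c(11L, 22L)) {
        n <- n + 1
        id <- sprintf("m%03d", n)
        ## mutator-entity genes 4 and 5 mutated only on background 1
        pos <- fpos
        if (lin_i == 1)
          pos <- c(pos, su_genes$start[3 + (n %% 2) + 1] + 3L)
        rows[[n]] <- data.frame(clone_id = id, population = pop,
                                day = day, position = pos, ref = "A",
                                alt = "G", class = "SNP")
      }
    }
  }
  calls <- ltsp_calls(do.call(rbind, rows))
  calls <- annotate_mutations(calls, su_genes)
  calls <- flag_mutators(calls, mutator_genes = character(0))
  lin <- infer_lineages(calls)
  grp <- list(repair_entity = su_genes$gene_id[4:5])
  res <- rnapc_locus_association(calls, lin,
                                 founder_genes = su_genes$gene_id[1],
                                 merge_groups = grp)
  ent <- res[res$locus == "repair_entity", ]
  expect_equal(nrow(ent), 2L)
  expect_true(any(ent$Q == 1))
})
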