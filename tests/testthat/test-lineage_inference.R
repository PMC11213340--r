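## helper: build an ltsp_calls object from compact clone descriptions
## (list of list(id, pop, day, pos = integer positions))
make_calls <- function(clones) {
  mut <- do.call(rbind, lapply(clones, function(cl) {
    if (length(cl$pos) == 0) return(NULL)
    data.frame(clone_id = cl$id, population = cl$pop, day = cl$day,
               position = cl$pos, ref = "A", alt = "G", class = "SNP",
               stringsAsFactors = FALSE)
  }))
  manifest <- do.call(rbind, lapply(clones, function(cl)
    data.frame(clone_id = cl$id, population = cl$pop, day = cl$day)))
  ltsp_calls(mut, clones = manifest)
}

test_that("mutation frequencies are carrier fractions per population-day", {
  clones <- c(
    lapply(1:3, function(i) list(id = paste0("a", i), pop = "1", day = 11L,
                                 pos = 100L)),
    lapply(4:10, function(i) list(id = paste0("a", i), pop = "1", day = 11L,
                                  pos = 200L)))
  calls <- make_calls(clones)
  fr <- mutation_frequencies(calls)
  expect_equal(fr$frequency[fr$key == "100:A>G"], 0.3)
  expect_equal(fr$frequency[fr$key == "200:A>G"], 0.7)
  ## a mutation absent from a day is reported at 0 on the dense grid
  clones2 <- c(clones, list(list(id = "b1", pop = "1", day = 22L,
                                 pos = 300L)))
  fr2 <- mutation_frequencies(make_calls(clones2))
  expect_equal(fr2$frequency[fr2$key == "100:A>G" & fr2$day == 22], 0)
})

test_that("Levenshtein distances match the DP oracle on canonical strings", {
  expect_equal(levenshtein_distance(character(0), character(0)), 0L)
  expect_equal(levenshtein_distance(sort_keys(c(1, 2)), sort_keys(c(1, 2))), 0L)
  ## superset gap
  expect_equal(levenshtein_distance(sort_keys(c(1, 2)),
                                    sort_keys(c(1, 2, 3))), 1L)
  ## {m1,m3} vs {m2,m3} under canonical order: one substitution
  expect_equal(levenshtein_distance(sort_keys(c(1, 3)),
                                    sort_keys(c(2, 3))), 1L)
})

test_that("parents minimize distance with day / shared-count tie-breaking", {
  alpha <- 10L; beta <- 20L; m1 <- 30L
  calls <- make_calls(list(
    list(id = "c1", pop = "1", day = 11L, pos = alpha),
    list(id = "c2", pop = "1", day = 11L, pos = beta),
    list(id = "c3", pop = "1", day = 32L, pos = c(alpha, m1))))
  edges <- infer_parents(calls)
  expect_equal(edges$parent_id[edges$clone_id == "c3"], "c1")
  expect_equal(edges$distance[edges$clone_id == "c3"], 1L)
  ## equal distance, different days: the earlier candidate wins
  calls2 <- make_calls(list(
    list(id = "e1", pop = "1", day = 11L, pos = alpha),
    list(id = "e2", pop = "1", day = 22L, pos = alpha),
    list(id = "e3", pop = "1", day = 32L, pos = c(alpha, m1))))
  edges2 <- infer_parents(calls2)
  expect_equal(edges2$parent_id[edges2$clone_id == "e3"], "e1")
  ## earliest-day clones attach to the population ancestor
  expect_true(is.na(edges2$parent_id[edges2$clone_id == "e1"]))
})

test_that("phylogenies are acyclic with day-monotone edges", {
  sim <- small_sim(21)
  edges <- infer_lineages(sim$calls)$edges
  has_parent <- !is.na(edges$parent_id)
  expect_true(all(edges$parent_day[has_parent] <= edges$day[has_parent]))
  ## following parents always terminates at a root
  parent <- setNames(edges$parent_id, edges$clone_id)
  for (id in sample(edges$clone_id, 25)) {
    steps <- 0L
    while (!is.na(id) && steps <= nrow(edges)) {
      id <- parent[[id]]
      steps <- steps + 1L
    }
    expect_true(is.na(id))
  }
})

test_that("populations with no 30% mutation yield only a pseudo-lineage", {
  ## 10 clones, each with a unique private mutation (frequency 0.1)
  clones <- lapply(1:10, function(i)
    list(id = paste0("u", i), pop = "1", day = c(11L, 22L)[(i %% 2) + 1],
         pos = 1000L + i))
  lin <- infer_lineages(make_calls(clones))
  expect_equal(sum(!lin$lineages$is_pseudo), 0L)
  expect_true(all(lin$assignments$is_pseudo))
})

test_that("a founding mutation must persist two time points to define a lineage", {
  ## 5/10 clones carry the mutation but only at day 11
  clones <- c(
    lapply(1:5, function(i) list(id = paste0("f", i), pop = "1", day = 11L,
                                 pos = 500L)),
    lapply(6:10, function(i) list(id = paste0("f", i), pop = "1",
                                  day = c(11L, 22L)[(i %% 2) + 1],
                                  pos = 600L + i)))
  lin <- infer_lineages(make_calls(clones))
  expect_equal(sum(!lin$lineages$is_pseudo), 0L)
})

test_that("Muller rows are clone fractions summing to one", {
  clones <- c(
    lapply(1:6, function(i) list(id = sprintf("m%02d", i), pop = "1",
                                 day = 11L, pos = 100L)),
    lapply(7:9, function(i) list(id = sprintf("m%02d", i), pop = "1",
                                 day = 11L, pos = 200L)),
    list(list(id = "m10", pop = "1", day = 11L, pos = integer(0))),
    ## second day so both mutations persist
    list(list(id = "m11", pop = "1", day = 22L, pos = 100L)),
    list(list(id = "m12", pop = "1", day = 22L, pos = 200L)))
  lin <- infer_lineages(make_calls(clones))
  mt <- lin$muller
  d11 <- mt[mt$day == 11, ]
  expect_setequal(round(d11$frequency, 6), c(0.6, 0.3, 0.1))
  sums <- tapply(mt$frequency, paste(mt$population, mt$day), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("simulated lineage structure is recovered from the clone sample", {
  sim <- simulate_ltsp(recovery_config(1))
  lin <- infer_lineages(sim$calls)
  truth <- sim$truth$clones
  ## lineage count: 3 per population
  expect_equal(sum(!lin$lineages$is_pseudo),
               3L * sim$config$n_populations)
  ## founder-key frequencies track the true sampled lineage composition
  fr <- mutation_frequencies(sim$calls)
  fk <- sim$truth$founders$key[1]
  for (pop in c("1", "3")) {
    lins <- unique(truth$lineage[truth$population == pop &
                                   truth$founder_label ==
                                     sim$truth$founders$label[1]])
    if (length(lins) == 0) next
    days <- sort(unique(truth$day[truth$population == pop]))
    for (d in sample(days, 3)) {
      in_pop_day <- truth$population == pop & truth$day == d
      expect_equal(
        fr$frequency[fr$population == pop & fr$key == fk & fr$day == d],
        sum(in_pop_day & truth$lineage %in% lins) / sum(in_pop_day))
    }
  }
  ## inferred parents lie on the clone's true lineage (strong signal)
  truth_lin <- setNames(truth$lineage, truth$clone_id)
  edges <- lin$edges
  informative <- !is.na(edges$parent_id) &
    !grepl("pseudo", truth_lin[edges$clone_id])
  agree <- truth_lin[edges$clone_id[informative]] ==
    truth_lin[edges$parent_id[informative]]
  expect_gt(mean(agree), 0.9)
  ## clone assignments match the true partition (adjusted for labels):
  ## every inferred non-pseudo lineage maps to one true lineage
  a <- lin$assignments
  for (lid in lin$lineages$lineage_id[!lin$lineages$is_pseudo]) {
    members <- a$clone_id[a$lineage_id == lid]
    expect_gt(max(table(truth_lin[members])) / length(members), 0.9)
  }
})

test_that("within-lineage mutation counts are non-decreasing in time", {
  sim <- simulate_ltsp(recovery_config(2))
  lin <- infer_lineages(sim$calls)
  acc <- mutation_accumulation(sim$calls, lineages = lin)
  acc <- acc[!grepl("pseudo", acc$lineage_id) & acc$n_clones >= 3, ]
  ## fit per-lineage slopes of mean mutations against day
  for (lid in unique(acc$lineage_id)) {
    g <- acc[acc$lineage_id == lid, ]
    if (nrow(g) < 4) next
    expect_gt(coef(lm(mean_mutations ~ day, data = g))[2], 0)
  }
})
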