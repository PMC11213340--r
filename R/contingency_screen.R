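## contingency_screen: candidate pair enumeration, lineage-level 2x2
## tables, Yule Q/Y/phi with one-sided significance + FDR, threshold
## selection, consensus reliable pairs, randomization-based functional
## enrichment, directionality inference and locus <-> lineage-defining
## mutation association.

#' Build the screening units (lineages + pseudo-lineages)
#'
#' Units are the independent evolutionary containers used for 2x2
#' contingency tables: non-mutator lineages plus pseudo-lineages.  By
#' default mutator lineages are removed entirely and mutator clones
#' never contribute to any cell.
#'
#' @param calls an annotated [ltsp_calls] object with mutator flags.
#' @param lineages an `ltsp_lineages` object.
#' @param exclude_mutator_lineages drop lineages whose clone majority is
#'   mutator (default `TRUE`).
#' @param exclude_mutator_clones drop individual mutator clones from the
#'   remaining units (default `TRUE`).
#' @return list with `units` (named list: unit id -> clone ids) and
#'   `clone_loci` (named list: clone id -> unique locus ids, unassigned
#'   excluded).
#' @export
screen_units <- function(calls, lineages,
                         exclude_mutator_lineages = TRUE,
                         exclude_mutator_clones = TRUE) {
  lin <- lineages$lineages
  a <- lineages$assignments
  cl <- calls$clones
  mut_flag <- cl$is_mutator
  mut_flag[is.na(mut_flag)] <- FALSE
  names(mut_flag) <- cl$clone_id
  keep_lin <- lin$lineage_id
  if (exclude_mutator_lineages)
    keep_lin <- lin$lineage_id[!lin$is_mutator]
  units <- lapply(stats::setNames(keep_lin, keep_lin), function(lid) {
    ids <- a$clone_id[a$lineage_id == lid]
    if (exclude_mutator_clones) ids <- ids[!mut_flag[ids]]
    ids
  })
  m <- calls$mutations
  m <- m[!is.na(m$locus_id) & m$locus_id != "unassigned", , drop = FALSE]
  clone_loci <- lapply(split(m$locus_id, m$clone_id), unique)
  list(units = units, clone_loci = clone_loci)
}

#' Enumerate candidate loci pairs for the contingency screen
#'
#' Candidate pairs are unordered pairs of convergently mutated loci
#' (mutated in at least `min_units` independent lineages/pseudo-lineages
#' or populations, excluding the lineage-founder genes) that are
#' co-mutated within at least one single non-mutator clone in at least
#' `min_units` screening units.
#'
#' @param calls an annotated [ltsp_calls] object with mutator flags.
#' @param lineages an `ltsp_lineages` object.
#' @param exclude locus ids excluded from the screen (the
#'   lineage-founding RNA-polymerase-core genes in the original design);
#'   default none.
#' @param min_units minimum independent units (default 2).
#' @param units optional precomputed [screen_units()] result.
#' @return data frame with columns `locus_a`, `locus_b`, `n_co_units`.
#' @export
enumerate_candidate_pairs <- function(calls, lineages, exclude = character(0),
                                      min_units = 2L, units = NULL) {
  conv_lin <- convergent_loci(calls, level = "lineage",
                              lineages = lineages, min_units = min_units)
  conv_pop <- convergent_loci(calls, level = "population",
                              min_units = min_units)
  eligible <- setdiff(union(conv_lin$convergent, conv_pop$convergent),
                      exclude)
  su <- units %||% screen_units(calls, lineages)
  tally <- new.env(parent = emptyenv())
  for (uid in names(su$units)) {
    seen <- character(0)
    for (id in su$units[[uid]]) {
      loci <- intersect(su$clone_loci[[id]] %||% character(0), eligible)
      if (length(loci) < 2L) next
      loci <- sort(loci)
      pr <- utils::combn(loci, 2L)
      seen <- union(seen, paste(pr[1, ], pr[2, ], sep = "\t"))
    }
    for (p in seen) tally[[p]] <- (tally[[p]] %||% 0L) + 1L
  }
  keys <- ls(tally)
  counts <- vapply(keys, function(k) tally[[k]], integer(1))
  keep <- counts >= min_units
  if (!any(keep))
    return(data.frame(locus_a = character(0), locus_b = character(0),
                      n_co_units = integer(0)))
  parts <- strsplit(keys[keep], "\t", fixed = TRUE)
  out <- data.frame(locus_a = vapply(parts, `[`, "", 1L),
                    locus_b = vapply(parts, `[`, "", 2L),
                    n_co_units = unname(counts[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$locus_a, out$locus_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Lineage-level 2x2 co-occurrence table for a loci pair
#'
#' Over the screening units: `a` = number of units containing a clone
#' mutated in both loci; `b` = units containing a clone mutated in the
#' first locus only; `c` = second locus only; `d` = units containing a
#' clone mutated in neither.  A unit can contribute to several cells
#' simultaneously.
#'
#' @param locus_a,locus_b locus ids.
#' @param units a [screen_units()] result.
#' @return named integer vector `c(a=, b=, c=, d=)`.
#' @export
build_pair_table <- function(locus_a, locus_b, units) {
  if (length(units$units) == 0L) stop_input("empty unit roster")
  a <- b <- cc <- d <- 0L
  for (uid in names(units$units)) {
    ids <- units$units[[uid]]
    if (length(ids) == 0L) next
    hasA <- vapply(ids, function(id)
      locus_a %in% (units$clone_loci[[id]] %||% character(0)), logical(1))
    hasB <- vapply(ids, function(id)
      locus_b %in% (units$clone_loci[[id]] %||% character(0)), logical(1))
    if (any(hasA & hasB)) a <- a + 1L
    if (any(hasA & !hasB)) b <- b + 1L
    if (any(!hasA & hasB)) cc <- cc + 1L
    if (any(!hasA & !hasB)) d <- d + 1L
  }
  c(a = a, b = b, c = cc, d = d)
}

#' Yule's Q, Y and phi for 2x2 tables
#'
#' `Q = (ad - bc) / (ad + bc)`;
#' `Y = (sqrt(ad) - sqrt(bc)) / (sqrt(ad) + sqrt(bc))`;
#' `phi = (ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d))`.
#' Undefined values (zero denominators) are returned as `NA`, flagged,
#' not raised.
#'
#' @param tables data frame (or named vector for a single table) with
#'   columns/elements `a`, `b`, `c`, `d`.
#' @return data frame with columns `a,b,c,d,Q,Y,phi`.
#' @export
yule_coefficients <- function(tables) {
  if (!is.data.frame(tables)) tables <- as.data.frame(as.list(tables))
  a <- as.numeric(tables$a); b <- as.numeric(tables$b)
  cc <- as.numeric(tables$c); d <- as.numeric(tables$d)
  ad <- a * d; bc <- b * cc
  Q <- ifelse(ad + bc > 0, (ad - bc) / (ad + bc), NA_real_)
  Y <- ifelse(sqrt(ad) + sqrt(bc) > 0,
              (sqrt(ad) - sqrt(bc)) / (sqrt(ad) + sqrt(bc)), NA_real_)
  marg <- (a + b) * (cc + d) * (a + cc) * (b + d)
  phi <- ifelse(marg > 0, (ad - bc) / sqrt(marg), NA_real_)
  out <- data.frame(a = a, b = b, c = cc, d = d, Q = Q, Y = Y, phi = phi)
  rownames(out) <- NULL
  out
}

## one-sided z-tests of positive association for the three coefficients.
## When any cell is 0 the test statistic (coefficient and its standard
## error) is computed on the +0.5-corrected table; reported coefficients
## stay on the raw counts.
.yule_pvalues <- function(tab) {
  n <- nrow(tab)
  p_Q <- p_Y <- p_phi <- rep(1, n)
  for (i in seq_len(n)) {
    cells <- as.numeric(tab[i, c("a", "b", "c", "d")])
    if (sum(cells) == 0) next
    if (any(cells == 0)) cells <- cells + 0.5
    a <- cells[1]; b <- cells[2]; cc <- cells[3]; d <- cells[4]
    ad <- a * d; bc <- b * cc
    inv <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
    Q <- (ad - bc) / (ad + bc)
    se_Q <- (1 - Q^2) / 2 * inv
    Y <- (sqrt(ad) - sqrt(bc)) / (sqrt(ad) + sqrt(bc))
    se_Y <- (1 - Y^2) / 4 * inv
    ntot <- a + b + cc + d
    phi <- (ad - bc) / sqrt((a + b) * (cc + d) * (a + cc) * (b + d))
    p_Q[i] <- stats::pnorm(Q / se_Q, lower.tail = FALSE)
    p_Y[i] <- stats::pnorm(Y / se_Y, lower.tail = FALSE)
    p_phi[i] <- stats::pnorm(phi * sqrt(ntot), lower.tail = FALSE)
  }
  data.frame(p_Q = p_Q, p_Y = p_Y, p_phi = p_phi)
}

#' One-sided association tests with FDR correction
#'
#' For each pair, tests positive association (one-sided, large-sample
#' z-statistics on the coefficient over its standard error;
#' `SE(Q) = ((1-Q^2)/2) sqrt(1/a+1/b+1/c+1/d)`, the analogous form for
#' Y, and `z = phi sqrt(n)` for phi; 0.5 added to every cell of the
#' test statistic when any cell is 0).  P-values are corrected per
#' coefficient across all tested pairs with Benjamini-Hochberg.
#'
#' @param results data frame containing columns `a,b,c,d` (and
#'   typically `Q,Y,phi` from [yule_coefficients()]).
#' @param alpha FDR level (default 0.05).
#' @return `results` augmented with `p_Q,p_Y,p_phi`, `q_Q,q_Y,q_phi`,
#'   `sig_Q,sig_Y,sig_phi`.
#' @export
test_association <- function(results, alpha = 0.05) {
  pv <- .yule_pvalues(results)
  results$p_Q <- pv$p_Q; results$p_Y <- pv$p_Y; results$p_phi <- pv$p_phi
  results$q_Q <- stats::p.adjust(results$p_Q, method = "BH")
  results$q_Y <- stats::p.adjust(results$p_Y, method = "BH")
  results$q_phi <- stats::p.adjust(results$p_phi, method = "BH")
  results$sig_Q <- results$q_Q <= alpha
  results$sig_Y <- results$q_Y <= alpha
  results$sig_phi <- results$q_phi <= alpha
  results
}

.pair_is_functional <- function(results, functional) {
  if (is.null(functional) || nrow(functional) == 0L)
    return(rep(FALSE, nrow(results)))
  pair_id(results$locus_a, results$locus_b) %in%
    pair_id(functional$locus_a, functional$locus_b)
}

#' Select coefficient cutoffs maximizing functional support
#'
#' Scans the sorted distinct values of each coefficient among the
#' FDR-significant pairs and returns the cutoff at which the highest
#' fraction of above-cutoff pairs carries a known functional
#' association; ties go to the lowest such cutoff.
#'
#' @param results tested association table (see [test_association()])
#'   with `locus_a`/`locus_b` columns.
#' @param functional functional pair table (see
#'   [read_functional_pairs()]); with an empty table thresholding is
#'   skipped with a warning and `NULL` returned.
#' @param coefficients which coefficients to threshold (default Q, Y).
#' @return named list of cutoffs (e.g. `list(Q = 0.8, Y = 0.5)`), or
#'   `NULL`.
#' @export
select_thresholds <- function(results, functional,
                              coefficients = c("Q", "Y")) {
  if (is.null(functional) || nrow(functional) == 0L) {
    warning("no functional pair table; threshold selection skipped",
            call. = FALSE)
    return(NULL)
  }
  is_fun <- .pair_is_functional(results, functional)
  out <- list()
  for (coef in coefficients) {
    sig <- results[[paste0("sig_", coef)]] & !is.na(results[[coef]])
    vals <- results[[coef]][sig]
    fn <- is_fun[sig]
    if (length(vals) == 0L) { out[[coef]] <- NA_real_; next }
    grid <- sort(unique(vals))
    frac <- vapply(grid, function(cut) mean(fn[vals >= cut]), numeric(1))
    best <- max(frac)
    out[[coef]] <- grid[which(frac == best)[1]]  # lowest cutoff at the max
  }
  out
}

#' Consensus reliable pairs
#'
#' A pair is reliable when it is FDR-significant for the phi coefficient
#' and exceeds the Q and Y cutoffs.
#'
#' @param results tested association table.
#' @param q_cutoff,y_cutoff coefficient cutoffs (defaults 0.8 / 0.5).
#' @return `results` with a logical `reliable` column added.
#' @export
consensus_reliable_pairs <- function(results, q_cutoff = 0.8,
                                     y_cutoff = 0.5) {
  results$reliable <- results$sig_phi &
    !is.na(results$Q) & results$Q >= q_cutoff &
    !is.na(results$Y) & results$Y >= y_cutoff
  results
}

#' Randomization test of functional enrichment
#'
#' The observed fraction of pairs with a known functional association is
#' compared with the fractions obtained in `n_rand` randomizations, each
#' drawing the same number of distinct random pairs from the candidate
#' loci.  The empirical p-value uses add-one smoothing,
#' `p = (1 + #(random >= observed)) / (n_rand + 1)`.
#'
#' @param pairs data frame of pairs (`locus_a`, `locus_b`), e.g. the
#'   reliable set.
#' @param candidate_loci character vector of loci pairs are drawn from.
#' @param functional functional pair table.
#' @param n_rand number of randomizations (default 1000).
#' @param seed optional RNG seed.
#' @return list with `observed_fraction`, `p_value`, `null_fractions`.
#' @export
functional_enrichment <- function(pairs, candidate_loci, functional,
                                  n_rand = 1000L, seed = NULL) {
  k <- nrow(pairs)
  m <- length(unique(candidate_loci))
  if (choose(m, 2) < k)
    stop_input("fewer possible pairs than requested: choose(", m,
               ", 2) < ", k)
  obs <- mean(.pair_is_functional(pairs, functional))
  loci <- sort(unique(candidate_loci))
  fun_ids <- if (is.null(functional) || nrow(functional) == 0L)
    character(0) else pair_id(functional$locus_a, functional$locus_b)
  null_fractions <- with_seed(seed, {
    vapply(seq_len(n_rand), function(r) {
      idx <- sample.int(choose(m, 2), k)  # distinct unordered pairs
      ## map linear index to (i, j), i < j
      j <- ceiling((1 + sqrt(1 + 8 * idx)) / 2)
      i <- idx - (j - 1) * (j - 2) / 2
      mean(pair_id(loci[i], loci[j]) %in% fun_ids)
    }, numeric(1))
  })
  list(observed_fraction = obs,
       p_value = (1 + sum(null_fractions >= obs)) / (n_rand + 1),
       null_fractions = null_fractions)
}

#' Infer the directionality of putative contingencies
#'
#' For each pair, only units containing a clone mutated in both loci are
#' informative.  Within such a unit the double-mutant clone's ancestor
#' chain is walked towards the root: the first ancestor carrying exactly
#' one of the two loci determines which locus came first in that unit;
#' an ancestor chain jumping from neither locus directly to both means
#' the mutations were only ever seen together there.  Units with
#' internally conflicting double mutants are conflicting.  Calls
#' combine across units: a direction is reported only when every
#' direction-informative unit agrees; `always_together` when no unit
#' ever separates the two; otherwise `ambiguous` (`n/a` with no
#' informative unit at all).
#'
#' @param pairs data frame with `locus_a`, `locus_b`.
#' @param units a [screen_units()] result.
#' @param edges phylogeny edges from [infer_parents()].
#' @return data frame with per-pair unit tallies and a `direction`
#'   column (`A_first`, `B_first`, `always_together`, `ambiguous`,
#'   `n/a`); `A` refers to `locus_a`.
#' @export
infer_directionality <- function(pairs, units, edges) {
  parent_map <- stats::setNames(edges$parent_id, edges$clone_id)
  loci_of <- units$clone_loci
  unit_verdict <- function(la, lb, ids) {
    verdicts <- character(0)
    for (id in ids) {
      ls0 <- loci_of[[id]] %||% character(0)
      if (!(la %in% ls0 && lb %in% ls0)) next
      v <- "together"
      anc <- parent_map[[id]]
      while (!is.null(anc) && !is.na(anc)) {
        ls <- loci_of[[anc]] %||% character(0)
        hasA <- la %in% ls; hasB <- lb %in% ls
        if (hasA && !hasB) { v <- "A"; break }
        if (hasB && !hasA) { v <- "B"; break }
        if (!hasA && !hasB) break  # co-acquired below this ancestor
        anc <- parent_map[[anc]]
      }
      verdicts <- c(verdicts, v)
    }
    if (length(verdicts) == 0L) return(NA_character_)
    dirs <- setdiff(unique(verdicts), "together")
    if (length(dirs) == 0L) return("together")
    if (length(dirs) == 1L) return(dirs)
    "conflicting"
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    la <- pairs$locus_a[i]; lb <- pairs$locus_b[i]
    verdicts <- vapply(names(units$units), function(uid)
      unit_verdict(la, lb, units$units[[uid]]), character(1))
    verdicts <- verdicts[!is.na(verdicts)]
    nA <- sum(verdicts == "A"); nB <- sum(verdicts == "B")
    nT <- sum(verdicts == "together")
    nC <- sum(verdicts == "conflicting")
    direction <- if (length(verdicts) == 0L) "n/a"
    else if (nC > 0L || (nA > 0L && nB > 0L)) "ambiguous"
    else if (nA > 0L) "A_first"
    else if (nB > 0L) "B_first"
    else "always_together"
    data.frame(locus_a = la, locus_b = lb,
               n_informative_units = length(verdicts),
               n_a_first = nA, n_b_first = nB, n_together = nT,
               n_conflicting = nC, direction = direction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Association between loci and specific lineage-defining mutations
#'
#' Pairs each (convergently mutated) locus with each lineage-defining
#' mutation found in the given founder genes, and computes the same 2x2
#' tables, Yule coefficients and one-sided FDR-corrected tests as the
#' pair screen, with lineages and pseudo-lineages as units.  Mutator
#' lineages and clones are included (the mutator trait itself associates
#' with a specific founding mutation).  A `merge_groups` list can merge
#' several gene loci into one entity (e.g. the three mismatch-repair
#' genes) before table building.
#'
#' @param calls an annotated [ltsp_calls] object with mutator flags.
#' @param lineages an `ltsp_lineages` object.
#' @param founder_genes character vector of genes whose lineage-defining
#'   mutations are screened (RNA-polymerase core genes in the original
#'   design).
#' @param merge_groups named list mapping an entity name to the gene
#'   loci it merges (default: none).
#' @param min_units minimum units a locus must be mutated in (default 2).
#' @param alpha FDR level.
#' @return data frame: `locus`, `defining_mutation` (mutation key),
#'   `defining_label`, `a,b,c,d`, coefficients, p/q-values and
#'   significance flags.
#' @export
rnapc_locus_association <- function(calls, lineages, founder_genes,
                                    merge_groups = NULL, min_units = 2L,
                                    alpha = 0.05) {
  su <- screen_units(calls, lineages,
                     exclude_mutator_lineages = FALSE,
                     exclude_mutator_clones = FALSE)
  ## lineage-defining mutations located in the founder genes
  lmap_keys <- list()
  for (lid in names(lineages$cofounders)) {
    keys <- lineages$cofounders[[lid]]
    pos <- .key_position(keys)
    in_founder <- vapply(seq_along(keys), function(i) {
      k <- keys[i]
      any(calls$mutations$key == k &
            calls$mutations$locus_id %in% founder_genes)
    }, logical(1))
    lmap_keys[[lid]] <- keys[in_founder]
  }
  defining <- sort(unique(unlist(lmap_keys)))
  if (length(defining) == 0L)
    return(data.frame())
  ## clone-level carriage of each defining mutation
  m <- calls$mutations
  carriers <- lapply(stats::setNames(defining, defining), function(k)
    unique(m$clone_id[m$key == k]))
  ## locus sets with merging applied; founder genes themselves excluded
  locus_of <- function(l) {
    if (!is.null(merge_groups))
      for (g in names(merge_groups))
        if (l %in% merge_groups[[g]]) return(g)
    l
  }
  clone_loci <- lapply(su$clone_loci, function(ls)
    unique(vapply(setdiff(ls, founder_genes), locus_of, character(1))))
  ## loci mutated in >= min_units units
  unit_of <- rep(names(su$units), lengths(su$units))
  clone_unit <- stats::setNames(unit_of, unlist(su$units))
  locus_units <- new.env(parent = emptyenv())
  for (id in names(clone_loci)) {
    u <- clone_unit[[id]]
    if (is.null(u) || is.na(u)) next
    for (l in clone_loci[[id]])
      locus_units[[l]] <- union(locus_units[[l]] %||% character(0), u)
  }
  loci <- sort(ls(locus_units))
  loci <- loci[vapply(loci, function(l)
    length(locus_units[[l]]) >= min_units, logical(1))]
  if (length(loci) == 0L) return(data.frame())
  rows <- list()
  for (k in defining) {
    has_def <- function(id) id %in% carriers[[k]]
    for (l in loci) {
      a <- b <- cc <- d <- 0L
      for (uid in names(su$units)) {
        ids <- su$units[[uid]]
        if (length(ids) == 0L) next
        hasL <- vapply(ids, function(id)
          l %in% (clone_loci[[id]] %||% character(0)), logical(1))
        hasD <- vapply(ids, has_def, logical(1))
        if (any(hasL & hasD)) a <- a + 1L
        if (any(hasL & !hasD)) b <- b + 1L
        if (any(!hasL & hasD)) cc <- cc + 1L
        if (any(!hasL & !hasD)) d <- d + 1L
      }
      rows[[length(rows) + 1L]] <-
        data.frame(locus = l, defining_mutation = k,
                   a = a, b = b, c = cc, d = d, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  co <- yule_coefficients(tab[, c("a", "b", "c", "d")])
  tab$Q <- co$Q; tab$Y <- co$Y; tab$phi <- co$phi
  tab <- test_association(tab, alpha = alpha)
  tab
}

#' Run the full contingency screen
#'
#' Orchestrates candidate pair enumeration, 2x2 table construction,
#' Yule coefficients, one-sided FDR-corrected tests, cutoff selection
#' (when a functional pair table is supplied), the consensus reliable
#' set, directionality inference and the randomization-based functional
#' enrichment test.
#'
#' @param calls an annotated [ltsp_calls] object with mutator flags.
#' @param lineages an `ltsp_lineages` object.
#' @param functional optional functional pair table.
#' @param exclude locus ids excluded from pairing (founder genes).
#' @param alpha FDR level (default 0.05).
#' @param q_cutoff,y_cutoff coefficient cutoffs; `NULL` (default) means
#'   select them from the functional table when available, else fall
#'   back to 0.8 / 0.5.
#' @param n_randomizations randomizations for the enrichment test.
#' @param seed RNG seed for the enrichment randomizations.
#' @return an object of class `ltsp_screen`: list with `results` (per
#'   pair: cells, coefficients, tests, `reliable`), `directionality`
#'   (reliable pairs), `thresholds`, `enrichment`, `candidate_loci`,
#'   `units` (unit ids), `alpha`.
#' @export
contingency_screen <- function(calls, lineages, functional = NULL,
                               exclude = character(0), alpha = 0.05,
                               q_cutoff = NULL, y_cutoff = NULL,
                               n_randomizations = 1000L, seed = NULL) {
  su <- screen_units(calls, lineages)
  pairs <- enumerate_candidate_pairs(calls, lineages, exclude = exclude,
                                     units = su)
  conv_lin <- convergent_loci(calls, level = "lineage",
                              lineages = lineages, min_units = 2L)
  conv_pop <- convergent_loci(calls, level = "population", min_units = 2L)
  candidate_loci <- setdiff(union(conv_lin$convergent, conv_pop$convergent),
                            exclude)
  if (nrow(pairs) == 0L) {
    empty <- data.frame(locus_a = character(0), locus_b = character(0))
    return(structure(list(results = empty, directionality = NULL,
                          thresholds = list(Q = q_cutoff %||% 0.8,
                                            Y = y_cutoff %||% 0.5),
                          enrichment = NULL,
                          candidate_loci = candidate_loci,
                          units = names(su$units), alpha = alpha),
                     class = "ltsp_screen"))
  }
  cells <- t(vapply(seq_len(nrow(pairs)), function(i)
    build_pair_table(pairs$locus_a[i], pairs$locus_b[i], su),
    integer(4)))
  res <- cbind(pairs[, c("locus_a", "locus_b", "n_co_units")],
               yule_coefficients(as.data.frame(cells)))
  res <- test_association(res, alpha = alpha)
  thresholds <- list(Q = q_cutoff, Y = y_cutoff)
  if (is.null(q_cutoff) || is.null(y_cutoff)) {
    sel <- if (!is.null(functional) && nrow(functional) > 0L)
      select_thresholds(res, functional) else NULL
    thresholds$Q <- q_cutoff %||% (sel$Q %||% 0.8)
    thresholds$Y <- y_cutoff %||% (sel$Y %||% 0.5)
  }
  res <- consensus_reliable_pairs(res, thresholds$Q, thresholds$Y)
  res$functional <- .pair_is_functional(res, functional)
  reliable <- res[res$reliable, , drop = FALSE]
  directionality <- if (nrow(reliable))
    infer_directionality(reliable, su, lineages$edges) else NULL
  enrichment <- NULL
  if (!is.null(functional) && nrow(reliable) > 0L &&
      choose(length(candidate_loci), 2) >= nrow(reliable)) {
    enrichment <- functional_enrichment(reliable, candidate_loci,
                                        functional,
                                        n_rand = n_randomizations,
                                        seed = seed)
  }
  structure(list(results = res, directionality = directionality,
                 thresholds = thresholds, enrichment = enrichment,
                 candidate_loci = candidate_loci,
                 units = names(su$units), alpha = alpha),
            class = "ltsp_screen")
}

#' @export
print.ltsp_screen <- function(x, ...) {
  cat("LTSP contingency screen\n")
  cat("  screening units:", length(x$units),
      " candidate loci:", length(x$candidate_loci),
      " tested pairs:", nrow(x$results), "\n")
  if (nrow(x$results)) {
    cat("  significant pairs: Q", sum(x$results$sig_Q),
        " Y", sum(x$results$sig_Y), " phi", sum(x$results$sig_phi), "\n")
    cat(sprintf("  cutoffs: Q >= %.2f, Y >= %.2f; reliable pairs: %d\n",
                x$thresholds$Q, x$thresholds$Y, sum(x$results$reliable)))
  }
  if (!is.null(x$directionality)) {
    tb <- table(x$directionality$direction)
    cat("  directionality:",
        paste(names(tb), as.integer(tb), sep = "=", collapse = ", "), "\n")
  }
  if (!is.null(x$enrichment))
    cat(sprintf("  functional fraction: %.3f (randomization p = %.4g)\n",
                x$enrichment$observed_fraction, x$enrichment$p_value))
  invisible(x)
}

#' @export
summary.ltsp_screen <- function(object, ...) {
  print(object)
  if (nrow(object$results)) {
    cat("\nTop pairs by Q:\n")
    ord <- order(-object$results$Q)
    print(utils::head(object$results[ord, c("locus_a", "locus_b", "a",
                                            "b", "c", "d", "Q", "Y",
                                            "phi", "reliable")], 10))
  }
  invisible(object$results)
}
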