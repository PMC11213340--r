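## convergence: locus assignment (genes + promoter/intergenic loci),
## convergently mutated loci across populations and lineages, and
## time-resolved convergence summaries.

#' Build the genomic locus map (genes and promoter loci)
#'
#' Loci are either genes (their coding interval) or promoters: each
#' intergenic gap is assigned, strand-aware, to the gene(s) whose 5' end
#' borders it.  A gap claimed by one gene becomes that gene's promoter
#' locus (`"<gene>_promoter"`); a gap between divergently transcribed
#' genes is split by proximity, with the exactly equidistant position
#' going to the lexicographically smaller gene id; a gap bordered only by
#' 3' ends is left unassigned.
#'
#' @param genes a `gene_models` data frame.
#' @param genome_length total genome length; defaults to the
#'   `genome_length` attribute of `genes`.
#' @return data frame with columns `locus_id`, `kind`
#'   (`"gene"`/`"promoter"`), `gene_id`, `start`, `end` (1-based,
#'   inclusive, non-overlapping).
#' @export
locus_map <- function(genes, genome_length = attr(genes, "genome_length")) {
  stopifnot(is.data.frame(genes), nrow(genes) >= 1L)
  g <- genes[order(genes$start), , drop = FALSE]
  loci <- data.frame(locus_id = g$gene_id, kind = "gene",
                     gene_id = g$gene_id, start = g$start, end = g$end,
                     stringsAsFactors = FALSE)
  ## intergenic gaps, including the two genome ends
  bounds <- data.frame(
    gap_start = c(1L, g$end + 1L),
    gap_end = c(g$start - 1L, genome_length %||% max(g$end)),
    left = c(NA_integer_, seq_len(nrow(g))),
    right = c(seq_len(nrow(g)), NA_integer_))
  prom <- list()
  for (i in seq_len(nrow(bounds))) {
    s <- bounds$gap_start[i]; e <- bounds$gap_end[i]
    if (is.na(s) || is.na(e) || s > e) next
    li <- bounds$left[i]; ri <- bounds$right[i]
    left_claims <- !is.na(li) && g$strand[li] == "-"   # 5' end on its right
    right_claims <- !is.na(ri) && g$strand[ri] == "+"  # 5' end on its left
    if (left_claims && right_claims) {
      ## divergent genes: split by proximity to the gene border
      dl <- function(p) p - g$end[li]
      dr <- function(p) g$start[ri] - p
      ## positions with dl < dr belong to the left gene
      cut <- floor((g$end[li] + g$start[ri]) / 2)  # last pos with dl <= dr
      mid_equidistant <- (g$end[li] + g$start[ri]) %% 2 == 0
      left_end <- min(e, cut)
      if (mid_equidistant && cut >= s && cut <= e) {
        ## the central position is exactly equidistant: tie-break
        winner <- if (g$gene_id[li] <= g$gene_id[ri]) "left" else "right"
        if (winner == "right") left_end <- cut - 1L
      }
      if (s <= left_end)
        prom[[length(prom) + 1L]] <-
          data.frame(locus_id = paste0(g$gene_id[li], "_promoter"),
                     kind = "promoter", gene_id = g$gene_id[li],
                     start = s, end = left_end, stringsAsFactors = FALSE)
      if (left_end + 1L <= e)
        prom[[length(prom) + 1L]] <-
          data.frame(locus_id = paste0(g$gene_id[ri], "_promoter"),
                     kind = "promoter", gene_id = g$gene_id[ri],
                     start = left_end + 1L, end = e,
                     stringsAsFactors = FALSE)
    } else if (left_claims || right_claims) {
      gi <- if (left_claims) li else ri
      prom[[length(prom) + 1L]] <-
        data.frame(locus_id = paste0(g$gene_id[gi], "_promoter"),
                   kind = "promoter", gene_id = g$gene_id[gi],
                   start = s, end = e, stringsAsFactors = FALSE)
    }
    ## neither claims (convergent 3' ends): positions stay unassigned
  }
  out <- rbind(loci, do.call(rbind, prom))
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign genomic positions to loci
#'
#' @param position numeric vector of 1-based positions.
#' @param lmap locus map from [locus_map()].
#' @return character vector of locus ids; positions covered by no locus
#'   are `"unassigned"`.
#' @export
assign_locus <- function(position, lmap) {
  idx <- findInterval(position, lmap$start)
  out <- rep("unassigned", length(position))
  hit <- idx >= 1L & !is.na(position)
  hit[hit] <- position[hit] <= lmap$end[idx[hit]]
  out[hit] <- lmap$locus_id[idx[hit]]
  out
}

## units for convergence counting: population labels, or lineage ids
## (lineages + pseudo-lineages)
.unit_of_clone <- function(calls, level, lineages) {
  cl <- calls$clones
  if (level == "population") {
    stats::setNames(cl$population, cl$clone_id)
  } else {
    if (is.null(lineages))
      stop_input("level = 'lineage' needs a lineages object")
    a <- lineages$assignments
    stats::setNames(a$lineage_id, a$clone_id)
  }
}

#' Convergently mutated loci across independent units
#'
#' Counts, per locus, the number of independent units (populations, or
#' lineages plus pseudo-lineages) that contain at least one non-mutator
#' clone mutated in the locus; identical mutations shared by ancestry
#' within one unit count once.  Returns the loci meeting `min_units` and
#' the fraction of all unique non-mutator mutation events falling within
#' them.
#'
#' @param calls an annotated [ltsp_calls] object with mutator flags.
#' @param level `"population"` or `"lineage"`.
#' @param lineages an `ltsp_lineages` object (required for
#'   `level = "lineage"`).
#' @param min_units minimum number of units (default 2).
#' @return an object of class `convergence_summary`: list with
#'   `per_locus` (locus_id, n_units), `convergent` (locus ids),
#'   `fraction_in_convergent`, `n_events`, `level`, `min_units`.
#' @export
convergent_loci <- function(calls, level = c("population", "lineage"),
                            lineages = NULL, min_units = 2L) {
  level <- match.arg(level)
  unit_map <- .unit_of_clone(calls, level, lineages)
  cl <- calls$clones
  mut_flag <- cl$is_mutator
  mut_flag[is.na(mut_flag)] <- FALSE
  nonmut <- cl$clone_id[!mut_flag]
  m <- calls$mutations[calls$mutations$clone_id %in% nonmut, , drop = FALSE]
  m <- m[!is.na(m$locus_id) & m$locus_id != "unassigned", , drop = FALSE]
  m$unit <- unit_map[m$clone_id]
  per_locus <- stats::aggregate(
    unit ~ locus_id, data = unique(m[, c("locus_id", "unit")]),
    FUN = length)
  names(per_locus)[2] <- "n_units"
  per_locus <- per_locus[order(-per_locus$n_units, per_locus$locus_id), ,
                         drop = FALSE]
  rownames(per_locus) <- NULL
  convergent <- per_locus$locus_id[per_locus$n_units >= min_units]
  ## fraction of unique non-mutator mutation events in convergent loci
  ev <- unique_nonmutator_events(calls)
  n_events <- nrow(ev)
  frac <- if (n_events > 0)
    mean(ev$locus_id %in% convergent) else NA_real_
  structure(list(per_locus = per_locus, convergent = convergent,
                 fraction_in_convergent = frac, n_events = n_events,
                 level = level, min_units = min_units, by_day = NULL),
            class = "convergence_summary")
}

#' @export
print.convergence_summary <- function(x, ...) {
  cat("Convergence summary (level = ", x$level, ")\n", sep = "")
  cat("  loci mutated in >= ", x$min_units, " units: ",
      length(x$convergent), "\n", sep = "")
  cat("  fraction of non-mutator mutation events in those loci: ",
      sprintf("%.3f", x$fraction_in_convergent), "\n", sep = "")
  invisible(x)
}

#' Per-time-point convergence category fractions
#'
#' Each unique non-mutator mutation event, dated by its
#' first-observation day, is categorized by the number of populations in
#' which its locus is mutated (1..n populations); per day the category
#' fractions sum to 1.  Events in unassigned loci are excluded.
#'
#' @param calls an annotated [ltsp_calls] object with mutator flags.
#' @return data frame with columns `day`, `n_populations`, `fraction`.
#' @export
convergence_fraction_by_timepoint <- function(calls) {
  summ <- convergent_loci(calls, level = "population", min_units = 1L)
  counts <- stats::setNames(summ$per_locus$n_units, summ$per_locus$locus_id)
  n_pops <- length(unique(calls$clones$population))
  ev <- unique_nonmutator_events(calls)
  ev <- ev[!is.na(ev$locus_id) & ev$locus_id != "unassigned", , drop = FALSE]
  if (nrow(ev) == 0L)
    return(data.frame(day = integer(0), n_populations = integer(0),
                      fraction = numeric(0)))
  ev$category <- counts[ev$locus_id]
  days <- sort(unique(ev$day))
  rows <- lapply(days, function(d) {
    e <- ev[ev$day == d, , drop = FALSE]
    tab <- tabulate(e$category, nbins = n_pops)
    data.frame(day = d, n_populations = seq_len(n_pops),
               fraction = tab / sum(tab))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean mutation accumulation over time
#'
#' Mean (and SD) number of mutation calls per non-mutator clone at each
#' sampling day, optionally per lineage.
#'
#' @param calls an [ltsp_calls] object with mutator flags.
#' @param lineages optional `ltsp_lineages` object; when supplied the
#'   summary is computed per lineage.
#' @return data frame with columns (`lineage_id`,) `day`, `mean_mutations`,
#'   `sd_mutations`, `n_clones`.
#' @export
mutation_accumulation <- function(calls, lineages = NULL) {
  cl <- calls$clones
  mut_flag <- cl$is_mutator
  mut_flag[is.na(mut_flag)] <- FALSE
  cl <- cl[!mut_flag, , drop = FALSE]
  counts <- table(calls$mutations$clone_id)
  cl$n_mut <- as.integer(counts[cl$clone_id])
  cl$n_mut[is.na(cl$n_mut)] <- 0L
  if (!is.null(lineages)) {
    a <- lineages$assignments
    cl$lineage_id <- stats::setNames(a$lineage_id, a$clone_id)[cl$clone_id]
    grp <- split(cl, list(cl$lineage_id, cl$day), drop = TRUE)
  } else {
    grp <- split(cl, cl$day)
  }
  rows <- lapply(grp, function(g) {
    r <- data.frame(day = g$day[1],
                    mean_mutations = mean(g$n_mut),
                    sd_mutations = stats::sd(g$n_mut),
                    n_clones = nrow(g))
    if (!is.null(lineages)) r <- cbind(lineage_id = g$lineage_id[1], r)
    r
  })
  out <- do.call(rbind, rows)
  out <- out[order(if (!is.null(lineages)) out$lineage_id else out$day,
                   out$day), , drop = FALSE]
  rownames(out) <- NULL
  out
}
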