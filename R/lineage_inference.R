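## lineage_inference: mutation frequency tracks, the >=30% filter,
## Levenshtein-based parent assignment, per-population phylogenies,
## lineage definition, pseudo-lineages and Muller tables.

#' Per-population mutation frequency tracks
#'
#' The frequency of a mutation at a sampling day is the fraction of that
#' day's sequenced clones (of the same population) carrying it.  The
#' grid is dense: every mutation observed in a population gets a
#' frequency (possibly 0) at every day sampled in that population.
#'
#' @param calls an [ltsp_calls] object.
#' @return data frame with columns `population`, `key`, `day`,
#'   `carriers`, `n_clones`, `frequency`.
#' @export
mutation_frequencies <- function(calls) {
  cl <- calls$clones
  m <- unique(calls$mutations[, c("population", "key", "clone_id", "day")])
  out <- lapply(split(seq_len(nrow(cl)), cl$population), function(idx) {
    pop <- cl$population[idx[1]]
    days <- sort(unique(cl$day[idx]))
    n_per_day <- table(factor(cl$day[idx], levels = days))
    mp <- m[m$population == pop, , drop = FALSE]
    keys <- sort(unique(mp$key))
    if (length(keys) == 0L) return(NULL)
    carr <- table(factor(mp$key, levels = keys),
                  factor(mp$day, levels = days))
    grid <- expand.grid(key = keys, day = days, stringsAsFactors = FALSE)
    grid$population <- pop
    grid$carriers <- as.vector(carr)
    grid$n_clones <- as.integer(n_per_day[as.character(grid$day)])
    grid$frequency <- grid$carriers / grid$n_clones
    grid[, c("population", "key", "day", "carriers", "n_clones",
             "frequency")]
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(population = character(0), key = character(0),
                      day = integer(0), carriers = integer(0),
                      n_clones = integer(0), frequency = numeric(0))
  rownames(out) <- NULL
  out
}

## peak (maximum over days) frequency per (population, key)
peak_frequencies <- function(freqs) {
  if (nrow(freqs) == 0L)
    return(data.frame(population = character(0), key = character(0),
                      peak = numeric(0)))
  agg <- stats::aggregate(frequency ~ population + key, data = freqs,
                          FUN = max)
  names(agg)[3] <- "peak"
  agg
}

#' Levenshtein distance between two clone mutation profiles
#'
#' Mutations are perceived as single characters and a clone's mutation
#' list as a string; the distance is the standard edit distance
#' (insertions, deletions, substitutions at unit cost).  Inputs are
#' canonicalized first (sorted by genomic position, then by the full
#' key), so the distance is well defined on sets; whenever one set
#' contains the other it equals the size of the symmetric difference.
#'
#' @param a,b character vectors of mutation keys (or arbitrary symbols).
#' @return non-negative integer.
#' @export
levenshtein_distance <- function(a, b) {
  a <- canonical_sort_keys(unique(a))
  b <- canonical_sort_keys(unique(b))
  syms <- sort(unique(c(a, b)))
  if (length(syms) == 0L) return(0L)
  chars <- vapply(seq_along(syms), function(i) intToUtf8(0x4DFF + i),
                  character(1))
  map <- stats::setNames(chars, syms)
  as.integer(utils::adist(paste(map[a], collapse = ""),
                          paste(map[b], collapse = "")))
}

## per-population canonical symbol strings for the filtered mutation sets
## of each clone (plus the empty ancestor string); shared by parent
## inference and tests
.clone_strings <- function(keys_by_clone, all_keys) {
  all_keys <- canonical_sort_keys(all_keys)
  chars <- vapply(seq_along(all_keys), function(i) intToUtf8(0x4DFF + i),
                  character(1))
  map <- stats::setNames(chars, all_keys)
  vapply(keys_by_clone, function(k) {
    paste(map[canonical_sort_keys(k)], collapse = "")
  }, character(1))
}

#' Infer the parent of every clone from Levenshtein distances
#'
#' Within each population, every clone is assigned the candidate parent
#' (a clone sampled at the same or an earlier day) minimizing the
#' Levenshtein distance between the filtered mutation profiles.  Ties
#' are broken by earlier day, then larger shared-mutation count, then
#' lexicographic clone id.  The population ancestor (empty mutation set)
#' is always a candidate; clones choosing it get `parent_id = NA`.
#' Same-day candidates are restricted to clones preceding the focal
#' clone in the (day, profile size, clone id) order, which guarantees an
#' acyclic, day-monotone phylogeny.
#'
#' @param calls an [ltsp_calls] object.
#' @param keep_keys data frame (`population`, `key`) of mutations passing
#'   the frequency filter, e.g. from [peak_frequencies()]; when `NULL`
#'   all mutations are used.
#' @return data frame of phylogeny edges: `population`, `clone_id`,
#'   `parent_id` (`NA` for the ancestor), `distance`, `day`,
#'   `parent_day`.
#' @export
infer_parents <- function(calls, keep_keys = NULL) {
  cl <- calls$clones
  m <- calls$mutations
  if (!is.null(keep_keys)) {
    keep <- paste(m$population, m$key) %in%
      paste(keep_keys$population, keep_keys$key)
    m <- m[keep, , drop = FALSE]
  }
  sets_all <- split(m$key, m$clone_id)
  out <- lapply(split(seq_len(nrow(cl)), cl$population), function(idx) {
    ids <- cl$clone_id[idx]
    days <- cl$day[idx]
    sets <- lapply(ids, function(id) unique(sets_all[[id]] %||% character(0)))
    keys <- unique(unlist(sets))
    strings <- .clone_strings(sets, keys)
    sizes <- lengths(sets)
    ## distance matrix incl. the ancestor (empty string) in row/col 1
    D <- utils::adist(c("", strings))
    ## shared mutation counts
    if (length(keys)) {
      M <- vapply(sets, function(k) keys %in% k, logical(length(keys)))
      M <- matrix(M, nrow = length(keys))
      S <- crossprod(M)
    } else {
      S <- matrix(0L, length(ids), length(ids))
    }
    ord <- order(days, sizes, ids)
    ord_rank <- integer(length(ord))
    ord_rank[ord] <- seq_along(ord)  # position in the (day, size, id) order
    parent <- character(length(ids)); pday <- integer(length(ids))
    dist_out <- integer(length(ids))
    for (i in seq_along(ids)) {
      cand <- which(days < days[i] |
                      (days == days[i] & ord_rank < ord_rank[i]))
      ## candidate table: ancestor (index 0) + candidate clones
      cd <- c(sizes[i], D[i + 1L, cand + 1L])
      cday <- c(-Inf, days[cand])
      cshared <- c(0L, S[i, cand])
      cid <- c("", ids[cand])
      best <- which(cd == min(cd))
      if (length(best) > 1L) best <- best[cday[best] == min(cday[best])]
      if (length(best) > 1L)
        best <- best[cshared[best] == max(cshared[best])]
      if (length(best) > 1L) best <- best[order(cid[best])][1]
      best <- best[1]
      parent[i] <- cid[best]
      pday[i] <- if (cid[best] == "") NA_integer_ else
        as.integer(cday[best])
      dist_out[i] <- as.integer(cd[best])
    }
    data.frame(population = cl$population[idx[1]], clone_id = ids,
               parent_id = ifelse(parent == "", NA_character_, parent),
               distance = dist_out, day = days, parent_day = pday,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Define lineages from phylogeny, frequency tracks and the 30% rule
#'
#' A lineage is founded by a mutation that (i) reached at least
#' `threshold` frequency in its population at some sampling day and
#' (ii) whose carriers are observed at two or more distinct sampling
#' days.  Walking each clone's ancestor path from the population root,
#' the first edge on which such a qualifying mutation is acquired
#' defines the clone's lineage; when several qualify on the same edge
#' the one with the highest peak frequency (ties: smallest genomic
#' position, then key) names the lineage and the others are recorded as
#' co-founders.  Clones whose path never acquires a qualifying mutation
#' go to their population's pseudo-lineage.  Qualifying mutations whose
#' resulting member set spans fewer than two days are removed and the
#' assignment recomputed, so every emitted lineage persists for at least
#' two time points.
#'
#' @param calls an [ltsp_calls] object.
#' @param edges phylogeny edges from [infer_parents()].
#' @param freqs frequency tracks from [mutation_frequencies()].
#' @param threshold founding-frequency threshold (default 0.30).
#' @return list with `lineages` (lineage table), `assignments`
#'   (`clone_id`, `lineage_id`, `is_pseudo`).
#' @export
define_lineages <- function(calls, edges, freqs, threshold = 0.30) {
  cl <- calls$clones
  m <- calls$mutations
  peaks <- peak_frequencies(freqs)
  sets_all <- split(m$key, m$clone_id)
  parent_map <- stats::setNames(edges$parent_id, edges$clone_id)

  assign_pop <- function(pop) {
    ids <- cl$clone_id[cl$population == pop]
    pk <- peaks[peaks$population == pop, , drop = FALSE]
    qual0 <- pk$key[pk$peak >= threshold]
    mp <- m[m$population == pop, , drop = FALSE]
    days_per_key <- lapply(split(mp$day, mp$key), unique)
    persistent <- names(days_per_key)[lengths(days_per_key) >= 2L]
    qual <- intersect(qual0, persistent)
    peak_of <- stats::setNames(pk$peak, pk$key)
    ## filtered mutation sets (the sets the phylogeny was built on)
    fsets <- lapply(ids, function(id)
      intersect(unique(sets_all[[id]] %||% character(0)), qual0))
    names(fsets) <- ids

    repeat {
      founding <- rep(NA_character_, length(ids))
      names(founding) <- ids
      memo <- new.env(parent = emptyenv())
      get_founding <- function(id) {
        if (!is.na(founding[[id]])) return(founding[[id]])
        if (!is.null(memo[[id]])) return(memo[[id]])
        p <- parent_map[[id]]
        anc <- if (is.na(p)) "" else get_founding(p)
        if (anc != "") { memo[[id]] <- anc; return(anc) }
        pset <- if (is.na(p)) character(0) else fsets[[p]]
        acquired <- intersect(setdiff(fsets[[id]], pset), qual)
        res <- if (length(acquired)) {
          pos <- .key_position(acquired)
          acquired[order(-peak_of[acquired], pos, acquired)][1]
        } else ""
        memo[[id]] <- res
        res
      }
      for (id in ids) founding[[id]] <- get_founding(id)
      ## persistence check on actual members
      ok <- TRUE
      for (k in unique(founding[founding != ""])) {
        mem <- ids[founding == k]
        if (length(unique(cl$day[match(mem, cl$clone_id)])) < 2L) {
          qual <- setdiff(qual, k)
          ok <- FALSE
        }
      }
      if (ok) break
    }
    founding
  }

  pops <- unique(cl$population)
  founding_all <- unlist(lapply(pops, assign_pop))
  cl_f <- founding_all[cl$clone_id]
  lineage_id <- ifelse(cl_f == "" | is.na(cl_f),
                       paste0(cl$population, ":pseudo"),
                       paste0(cl$population, ":", cl_f))
  assignments <- data.frame(clone_id = cl$clone_id,
                            lineage_id = lineage_id,
                            is_pseudo = cl_f == "" | is.na(cl_f),
                            stringsAsFactors = FALSE)
  ## lineage table
  mut_flag <- cl$is_mutator
  mut_flag[is.na(mut_flag)] <- FALSE
  rows <- lapply(split(seq_len(nrow(cl)), lineage_id), function(idx) {
    lid <- lineage_id[idx[1]]
    pop <- cl$population[idx[1]]
    pseudo <- assignments$is_pseudo[idx[1]]
    fkey <- if (pseudo) NA_character_ else cl_f[idx[1]]
    data.frame(lineage_id = lid, population = pop,
               founding_key = fkey,
               is_pseudo = pseudo,
               n_clones = length(idx),
               n_mutator_clones = sum(mut_flag[idx]),
               is_mutator = mean(mut_flag[idx]) > 0.5,
               first_day = min(cl$day[idx]),
               last_day = max(cl$day[idx]),
               stringsAsFactors = FALSE)
  })
  lin <- do.call(rbind, rows)
  lin <- lin[order(lin$population, lin$is_pseudo, lin$founding_key), ,
             drop = FALSE]
  rownames(lin) <- NULL
  list(lineages = lin, assignments = assignments)
}

## co-founding keys (all qualifying mutations acquired on the founding
## edge) per lineage; used to label lineages and find lineage-defining
## mutations in particular genes
.cofounders <- function(calls, edges, freqs, lineages, threshold) {
  m <- calls$mutations
  peaks <- peak_frequencies(freqs)
  qual0 <- paste(peaks$population, peaks$key)[peaks$peak >= threshold]
  sets_all <- split(m$key, m$clone_id)
  parent_map <- stats::setNames(edges$parent_id, edges$clone_id)
  pop_of <- stats::setNames(calls$clones$population,
                            calls$clones$clone_id)
  a <- lineages$assignments
  lin_of <- stats::setNames(a$lineage_id, a$clone_id)
  out <- list()
  for (i in seq_len(nrow(lineages$lineages))) {
    L <- lineages$lineages[i, ]
    if (L$is_pseudo) next
    members <- a$clone_id[a$lineage_id == L$lineage_id]
    ## founding edges: members whose parent is outside the lineage
    co <- character(0)
    for (id in members) {
      p <- parent_map[[id]]
      outside <- is.na(p) || !identical(lin_of[[p]], L$lineage_id)
      if (!outside) next
      pset <- if (is.na(p)) character(0) else
        unique(sets_all[[p]] %||% character(0))
      acq <- setdiff(unique(sets_all[[id]] %||% character(0)), pset)
      acq <- acq[paste(L$population, acq) %in% qual0]
      co <- union(co, acq)
    }
    out[[L$lineage_id]] <- canonical_sort_keys(co)
  }
  out
}

#' Per-day lineage relative frequencies (Muller table)
#'
#' For each population and sampling day, a lineage's frequency is the
#' fraction of that day's sequenced clones assigned to it; rows per
#' population-day sum to 1, the pseudo-lineage included.
#'
#' @param lineages output of [define_lineages()] (or an `ltsp_lineages`
#'   object).
#' @param calls the matching [ltsp_calls] object.
#' @return data frame with columns `population`, `day`, `lineage_id`,
#'   `frequency`.
#' @export
muller_table <- function(lineages, calls) {
  a <- lineages$assignments
  cl <- calls$clones
  lin_of <- stats::setNames(a$lineage_id, a$clone_id)
  cl$lineage_id <- lin_of[cl$clone_id]
  out <- lapply(split(cl, cl$population), function(g) {
    lids <- sort(unique(
      lineages$lineages$lineage_id[lineages$lineages$population ==
                                     g$population[1]]))
    days <- sort(unique(g$day))
    grid <- expand.grid(lineage_id = lids, day = days,
                        stringsAsFactors = FALSE)
    grid$population <- g$population[1]
    tab <- table(factor(g$lineage_id, levels = lids),
                 factor(g$day, levels = days))
    n_day <- table(factor(g$day, levels = days))
    grid$frequency <- as.vector(tab) /
      as.integer(n_day[as.character(grid$day)])
    grid[, c("population", "day", "lineage_id", "frequency")]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Full lineage-inference pipeline
#'
#' Computes mutation frequency tracks, applies the founding-frequency
#' filter, infers Levenshtein parents, defines lineages and
#' pseudo-lineages, and tabulates the Muller table.
#'
#' @param calls an [ltsp_calls] object.
#' @param threshold founding-frequency threshold (default 0.30).
#' @return an object of class `ltsp_lineages`: list with `lineages`,
#'   `assignments`, `edges`, `frequencies`, `muller`, `cofounders`,
#'   `assigned_fraction`, `threshold`.
#' @export
infer_lineages <- function(calls, threshold = 0.30) {
  stopifnot(inherits(calls, "ltsp_calls"))
  freqs <- mutation_frequencies(calls)
  peaks <- peak_frequencies(freqs)
  keep <- peaks[peaks$peak >= threshold, c("population", "key")]
  edges <- infer_parents(calls, keep_keys = keep)
  defs <- define_lineages(calls, edges, freqs, threshold)
  res <- structure(list(lineages = defs$lineages,
                        assignments = defs$assignments,
                        edges = edges, frequencies = freqs,
                        muller = NULL, cofounders = NULL,
                        assigned_fraction =
                          mean(!defs$assignments$is_pseudo),
                        threshold = threshold),
                   class = "ltsp_lineages")
  res$muller <- muller_table(res, calls)
  res$cofounders <- .cofounders(calls, edges, freqs, res, threshold)
  res
}

#' @export
print.ltsp_lineages <- function(x, ...) {
  lin <- x$lineages[!x$lineages$is_pseudo, , drop = FALSE]
  cat("LTSP lineage structure\n")
  cat("  populations:", length(unique(x$lineages$population)),
      " lineages:", nrow(lin),
      " pseudo-lineages:", sum(x$lineages$is_pseudo), "\n")
  cat(sprintf("  clones assigned to a lineage: %.1f%%\n",
              100 * x$assigned_fraction))
  invisible(x)
}

#' @export
summary.ltsp_lineages <- function(object, ...) {
  print(object)
  cat("\nLineage table:\n")
  print(object$lineages)
  invisible(object$lineages)
}

#' Muller plot of lineage frequencies
#'
#' Minimal stacked-area rendering of the Muller table, one panel per
#' population, on a log-scaled day axis.
#'
#' @param x an `ltsp_lineages` object.
#' @param ... unused.
#' @export
plot.ltsp_lineages <- function(x, ...) {
  mt <- x$muller
  pops <- unique(mt$population)
  old <- graphics::par(mfrow = c(length(pops), 1),
                       mar = c(2.5, 3.5, 1.5, 0.5))
  on.exit(graphics::par(old))
  for (pop in pops) {
    g <- mt[mt$population == pop, , drop = FALSE]
    days <- sort(unique(g$day))
    lids <- unique(g$lineage_id)
    f <- matrix(0, length(lids), length(days),
                dimnames = list(lids, days))
    for (i in seq_len(nrow(g)))
      f[g$lineage_id[i], as.character(g$day[i])] <- g$frequency[i]
    cum <- apply(f, 2, cumsum)
    cols <- grDevices::hcl.colors(length(lids), "Dark 3")
    graphics::plot(NA, xlim = range(log10(days)), ylim = c(0, 1),
                   xlab = "", ylab = "frequency", main = pop, xaxt = "n")
    graphics::axis(1, at = log10(days), labels = days, cex.axis = 0.7)
    lower <- rep(0, length(days))
    for (i in seq_len(nrow(cum))) {
      graphics::polygon(c(log10(days), rev(log10(days))),
                        c(cum[i, ], rev(lower)), col = cols[i],
                        border = NA)
      lower <- cum[i, ]
    }
  }
  invisible(x)
}
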