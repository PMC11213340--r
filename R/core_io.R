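## core_io: domain containers and readers/writers for mutation tables,
## genome annotation, functional-pair tables and result tables.

.MUTATION_CLASSES <- c("SNP", "small_indel", "large_deletion",
                       "amplification", "mobile_element")
.CODING_EFFECTS <- c("synonymous", "nonsynonymous", "noncoding",
                     "indel_or_structural")

#' Default mismatch-repair / proofreading gene list used to flag mutators
#' @export
DEFAULT_MUTATOR_GENES <- c("mutS", "mutL", "mutH", "dnaQ")

new_ltsp_calls <- function(mutations, clones) {
  structure(list(mutations = mutations, clones = clones),
            class = "ltsp_calls")
}

#' Assemble a clone/mutation container from data frames
#'
#' The central data container of the package: one data frame of mutation
#' calls (one row per mutation per clone) plus one data frame of clones
#' (one row per sequenced isolate, including clones with zero mutations).
#'
#' @param mutations data frame with columns `clone_id`, `population`,
#'   `day`, `position`, `ref`, `alt`, `class` (and optionally `locus_id`,
#'   `coding_effect`).
#' @param clones optional clone manifest (`clone_id`, `population`, `day`);
#'   when `NULL` it is derived from the mutation rows.  Supplying a
#'   manifest retains sequenced clones that acquired no mutations.
#' @return an object of class `ltsp_calls`.
#' @export
ltsp_calls <- function(mutations, clones = NULL) {
  mutations <- as.data.frame(mutations, stringsAsFactors = FALSE)
  req <- c("clone_id", "population", "day", "position", "ref", "alt", "class")
  miss <- setdiff(req, names(mutations))
  if (length(miss))
    stop_input("mutation table is missing required column(s): ",
               paste(miss, collapse = ", "))
  mutations$clone_id <- as.character(mutations$clone_id)
  mutations$population <- as.character(mutations$population)
  mutations$day <- as.integer(mutations$day)
  mutations$position <- as.numeric(mutations$position)
  if (any(!is.na(mutations$position) & mutations$position < 1))
    stop_input("genomic positions must be >= 1")
  bad_class <- setdiff(unique(mutations$class), .MUTATION_CLASSES)
  if (length(bad_class))
    stop_input("unknown mutation class(es): ", paste(bad_class, collapse = ", "))
  if (is.null(mutations$locus_id)) mutations$locus_id <- NA_character_
  if (is.null(mutations$coding_effect)) mutations$coding_effect <- NA_character_
  mutations$key <- mutation_key(mutations$position, mutations$ref,
                                mutations$alt)

  ## collapse duplicated calls (clone, position, alt)
  dup <- duplicated(mutations[, c("clone_id", "position", "alt")])
  if (any(dup)) {
    warning(sum(dup), " duplicated mutation row(s) collapsed", call. = FALSE)
    mutations <- mutations[!dup, , drop = FALSE]
  }

  from_rows <- unique(mutations[, c("clone_id", "population", "day")])
  if (anyDuplicated(from_rows$clone_id))
    stop_input("clone(s) listed with conflicting population/day metadata: ",
               paste(unique(from_rows$clone_id[duplicated(from_rows$clone_id)]),
                     collapse = ", "))
  if (is.null(clones)) {
    clones <- from_rows
  } else {
    clones <- as.data.frame(clones, stringsAsFactors = FALSE)
    if (!all(c("clone_id", "population", "day") %in% names(clones)))
      stop_input("clone manifest needs columns clone_id, population, day")
    clones$clone_id <- as.character(clones$clone_id)
    clones$population <- as.character(clones$population)
    clones$day <- as.integer(clones$day)
    orphan <- setdiff(from_rows$clone_id, clones$clone_id)
    if (length(orphan))
      stop_input("mutation rows reference clones absent from the manifest: ",
                 paste(utils::head(orphan, 5), collapse = ", "))
  }
  clones <- clones[order(clones$population, clones$day, clones$clone_id), ,
                   drop = FALSE]
  rownames(clones) <- NULL
  if (is.null(clones$is_mutator)) clones$is_mutator <- NA
  if (is.null(clones$lineage_id)) clones$lineage_id <- NA_character_
  rownames(mutations) <- NULL
  new_ltsp_calls(mutations, clones)
}

#' Read a per-clone mutation table (S2-style TSV)
#'
#' One row per mutation call per clone.  The column dialect of exported
#' call tables varies between pipelines, so the mapping from the
#' canonical column names to the file's column names is configurable.
#'
#' @param path path to a tab-separated file with a header line.
#' @param schema named character vector mapping canonical names
#'   (`clone_id`, `population`, `day`, `position`, `ref`, `alt`, `class`,
#'   optionally `gene`, `effect`) to the file's column names.  Defaults to
#'   the identity mapping.
#' @param clone_manifest optional data frame (or TSV path) listing all
#'   sequenced clones (`clone_id`, `population`, `day`); clones present in
#'   the manifest but absent from the table are retained as empty clones.
#' @return an [ltsp_calls] object.
#' @export
read_mutation_table <- function(path, schema = NULL, clone_manifest = NULL) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  canon <- c("clone_id", "population", "day", "position", "ref", "alt",
             "class", "gene", "effect")
  schema <- schema %||% stats::setNames(canon, canon)
  required <- c("clone_id", "population", "day", "position", "ref", "alt",
                "class")
  lookup <- function(col) {
    if (col %in% names(schema)) schema[[col]] else col
  }
  for (col in required) {
    if (!lookup(col) %in% names(raw))
      stop_input("mutation table is missing required column(s): ",
                 lookup(col))
  }
  get_col <- function(col) {
    fc <- lookup(col)
    if (fc %in% names(raw)) raw[[fc]] else NULL
  }
  pos_raw <- get_col("position")
  pos <- suppressWarnings(as.numeric(pos_raw))
  bad <- which(is.na(pos) | pos < 1 | pos != floor(pos))
  if (length(bad))
    stop_input("malformed genomic coordinate on line(s): ",
               paste(bad + 1L, collapse = ", "))  # +1 for the header line
  mutations <- data.frame(
    clone_id = as.character(get_col("clone_id")),
    population = as.character(get_col("population")),
    day = as.integer(get_col("day")),
    position = pos,
    ref = as.character(get_col("ref")),
    alt = as.character(get_col("alt")),
    class = as.character(get_col("class")),
    stringsAsFactors = FALSE)
  gene <- get_col("gene"); effect <- get_col("effect")
  if (!is.null(gene)) mutations$locus_id <- as.character(gene)
  if (!is.null(effect)) mutations$coding_effect <- as.character(effect)
  if (is.character(clone_manifest) && length(clone_manifest) == 1L)
    clone_manifest <- utils::read.delim(clone_manifest,
                                        stringsAsFactors = FALSE)
  ltsp_calls(mutations, clones = clone_manifest)
}

#' Write a mutation table to TSV
#'
#' Inverse of [read_mutation_table()]; re-reading the emitted file
#' reproduces the in-memory calls.
#'
#' @param calls an [ltsp_calls] object.
#' @param path output file.
#' @param manifest_path optional path for the clone manifest TSV.
#' @export
write_mutation_table <- function(calls, path, manifest_path = NULL) {
  stopifnot(inherits(calls, "ltsp_calls"))
  cols <- c("clone_id", "population", "day", "position", "ref", "alt",
            "class")
  extra <- intersect(c("locus_id", "coding_effect"),
                     names(calls$mutations))
  out <- calls$mutations[, c(cols, extra), drop = FALSE]
  names(out)[names(out) == "locus_id"] <- "gene"
  names(out)[names(out) == "coding_effect"] <- "effect"
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(manifest_path))
    utils::write.table(calls$clones[, c("clone_id", "population", "day")],
                       manifest_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' @export
print.ltsp_calls <- function(x, ...) {
  cat("LTSP clone calls\n")
  cat("  populations:", length(unique(x$clones$population)),
      " clones:", nrow(x$clones),
      " mutation calls:", nrow(x$mutations), "\n")
  cat("  sampling days:", paste(sort(unique(x$clones$day)), collapse = ", "),
      "\n")
  if (!all(is.na(x$clones$is_mutator)))
    cat("  mutator clones:", sum(x$clones$is_mutator, na.rm = TRUE), "\n")
  invisible(x)
}

## ---------------------------------------------------------------------
## genome annotation

new_gene_models <- function(df, genome_seq, genome_length) {
  structure(df, genome_seq = genome_seq, genome_length = genome_length,
            class = c("gene_models", "data.frame"))
}

#' Read a genome annotation (GFF3 + FASTA) into gene models
#'
#' One row per protein-coding gene: strand, 1-based inclusive coding
#' interval and the coding sequence read 5'->3' (minus-strand genes are
#' reverse-complemented).  Multi-part CDS features sharing a gene id are
#' concatenated in translation order.  Genes whose coding length is not a
#' multiple of 3 are skipped with a warning (pseudogene handling).
#' A single reference sequence is assumed.
#'
#' @param gff path to a GFF3 file; features of `feature_type` are used.
#' @param fasta path to the matching FASTA file (one sequence).
#' @param feature_type GFF3 feature type to read (default `"CDS"`).
#' @param id_fields attribute names tried, in order, for the gene id.
#' @return a `gene_models` data frame with columns `gene_id`, `strand`,
#'   `start`, `end`, `seq`; the genome sequence and its length are kept as
#'   attributes `genome_seq` / `genome_length`.
#' @export
read_annotation <- function(gff, fasta, feature_type = "CDS",
                            id_fields = c("gene", "Name", "ID",
                                          "locus_tag")) {
  if (!file.exists(gff)) stop_input("no such file: ", gff)
  if (!file.exists(fasta)) stop_input("no such file: ", fasta)
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) != 1L)
    stop_input("expected a single reference sequence, got ", length(seqs))
  genome_seq <- as.character(seqs[[1]])
  gr <- rtracklayer::import(gff)
  gr <- gr[as.character(gr$type) == feature_type]
  if (length(gr) == 0L)
    stop_input("annotation contains no '", feature_type, "' features")
  meta <- S4Vectors::mcols(gr)
  ids <- rep(NA_character_, length(gr))
  for (f in id_fields) {
    if (f %in% names(meta)) {
      v <- as.character(meta[[f]])
      ids[is.na(ids) & !is.na(v)] <- v[is.na(ids) & !is.na(v)]
    }
  }
  if (anyNA(ids))
    stop_input("coding features without a gene identifier (tried: ",
               paste(id_fields, collapse = ", "), ")")
  df <- data.frame(gene_id = ids,
                   strand = as.character(BiocGenerics::strand(gr)),
                   start = BiocGenerics::start(gr),
                   end = BiocGenerics::end(gr),
                   stringsAsFactors = FALSE)
  if (any(!df$strand %in% c("+", "-")))
    stop_input("coding features must be stranded (+/-)")
  ## assemble per-gene coding sequence, concatenating CDS parts in
  ## translation order
  out <- lapply(split(df, df$gene_id), function(g) {
    g <- g[order(g$start), , drop = FALSE]
    parts <- substring(genome_seq, g$start, g$end)
    if (g$strand[1] == "-") {
      cds <- paste(rev(revcomp(parts)), collapse = "")
    } else {
      cds <- paste(parts, collapse = "")
    }
    data.frame(gene_id = g$gene_id[1], strand = g$strand[1],
               start = min(g$start), end = max(g$end), seq = toupper(cds),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  bad <- nchar(out$seq) %% 3L != 0L
  if (any(bad)) {
    warning("skipping ", sum(bad),
            " gene(s) with coding length not divisible by 3: ",
            paste(utils::head(out$gene_id[bad], 5), collapse = ", "),
            call. = FALSE)
    out <- out[!bad, , drop = FALSE]
  }
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  new_gene_models(out, genome_seq, nchar(genome_seq))
}

#' Read a functional-association pair table (STRING-style TSV)
#'
#' Two columns of locus ids; pairs are unordered, self-pairs are dropped
#' and duplicates (in either orientation) collapsed.
#'
#' @param path two-column TSV (header optional; the first two columns are
#'   used).
#' @return data frame with columns `locus_a`, `locus_b` (lexicographically
#'   ordered within each row).
#' @export
read_functional_pairs <- function(path) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           header = TRUE)
  if (ncol(raw) < 2L) stop_input("functional pair table needs two columns")
  functional_pair_table(raw[[1]], raw[[2]])
}

#' Construct a functional pair table from two locus-id vectors
#' @param a,b character vectors of locus ids (paired elementwise).
#' @return canonicalized pair data frame (see [read_functional_pairs()]).
#' @export
functional_pair_table <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  keep <- !is.na(a) & !is.na(b) & a != b
  df <- data.frame(locus_a = pmin(a[keep], b[keep]),
                   locus_b = pmax(a[keep], b[keep]),
                   stringsAsFactors = FALSE)
  df <- unique(df)
  rownames(df) <- NULL
  df
}

## ---------------------------------------------------------------------
## result writing

#' Write analysis result tables to a directory
#'
#' Emits whichever result sets are supplied, under fixed file names:
#' lineage table (`lineage_table.tsv`), clone assignments
#' (`clone_assignments.tsv`), Muller table (`muller_table.csv`),
#' phylogeny edges (`phylogeny_edges.tsv`), convergence tables
#' (`convergence_loci.tsv`, `convergence_by_day.tsv`), association table
#' (`association_table.tsv`), directionality table
#' (`directionality.tsv`) and the contingency network edge list
#' (`contingency_network.tsv`: locus_A, locus_B, direction).
#' Re-reading any emitted table reproduces the in-memory values.
#'
#' @param outdir output directory (created if needed).
#' @param lineages an `ltsp_lineages` object (optional).
#' @param screen an `ltsp_screen` object (optional).
#' @param convergence a `convergence_summary` object (optional).
#' @param dnds a data frame of dN/dS results (optional,
#'   `dnds_table.tsv`).
#' @return invisibly, the paths written.
#' @export
write_results <- function(outdir, lineages = NULL, screen = NULL,
                          convergence = NULL, dnds = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop_input("cannot create directory: ", outdir)
  paths <- character(0)
  wtsv <- function(df, file) {
    p <- file.path(outdir, file)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (!is.null(lineages)) {
    stopifnot(inherits(lineages, "ltsp_lineages"))
    wtsv(lineages$lineages, "lineage_table.tsv")
    wtsv(lineages$assignments, "clone_assignments.tsv")
    wtsv(lineages$edges, "phylogeny_edges.tsv")
    p <- file.path(outdir, "muller_table.csv")
    utils::write.csv(lineages$muller, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(convergence)) {
    stopifnot(inherits(convergence, "convergence_summary"))
    wtsv(convergence$per_locus, "convergence_loci.tsv")
    if (!is.null(convergence$by_day))
      wtsv(convergence$by_day, "convergence_by_day.tsv")
  }
  if (!is.null(screen)) {
    stopifnot(inherits(screen, "ltsp_screen"))
    wtsv(screen$results, "association_table.tsv")
    if (!is.null(screen$directionality)) {
      wtsv(screen$directionality, "directionality.tsv")
      net <- screen$directionality[, c("locus_a", "locus_b", "direction")]
      names(net) <- c("locus_A", "locus_B", "direction")
      wtsv(net, "contingency_network.tsv")
    } else {
      ## header-only network when nothing was reliable
      net <- data.frame(locus_A = character(0), locus_B = character(0),
                        direction = character(0))
      wtsv(net, "contingency_network.tsv")
    }
  }
  if (!is.null(dnds)) wtsv(dnds, "dnds_table.tsv")
  invisible(paths)
}
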