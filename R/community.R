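# Clone-library processing for ppk1-based Accumulibacter profiling:
# pairwise global-alignment identity, greedy OTU clustering at a fixed
# threshold (99% by convention), clade assignment against a labelled
# reference panel, and per-run composition tables.

clade_vocabulary <- c(
  paste0("I", LETTERS[1:5]),                       # IA..IE
  paste0("II", LETTERS[1:8]), "II-I"               # IIA..IIH, II-I
)

#' Construct a clone library
#'
#' @param run_id Run identifier.
#' @param sequences Named character vector of nucleotide sequences
#'   (names are clone ids, unique; alphabet A/C/G/T/N).
#' @return A list of class `clone_library`.
#' @export
clone_library <- function(run_id, sequences) {
  if (!is.character(sequences) || length(sequences) == 0L) {
    stop("'sequences' must be a non-empty named character vector",
         call. = FALSE)
  }
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids)) || anyDuplicated(ids)) {
    stop("clone ids must be unique and non-empty", call. = FALSE)
  }
  if (any(!nzchar(sequences))) stop("empty sequence", call. = FALSE)
  bad <- grepl("[^ACGTNacgtn]", sequences)
  if (any(bad)) {
    stop("invalid nucleotide characters in clones: ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  structure(list(run_id = run_id, sequences = toupper(sequences)),
            class = "clone_library")
}

# shared alignment scoring: match +2 / mismatch -1, affine gaps (open 5,
# extend 2) so substitutions are preferred over gaps for equal-length inputs
align_global <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 2, mismatch = -1, baseOnly = FALSE)
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global", substitutionMatrix = mat,
    gapOpening = 5, gapExtension = 2)
}

#' Pairwise nucleotide identity under global alignment
#'
#' Needleman-Wunsch global alignment (match +2, mismatch -1, gap open 5 /
#' extend 2); identity is the number of matching positions divided by the
#' full alignment length, so gap columns count as mismatches. Symmetric in
#' its arguments.
#'
#' @param seq_a,seq_b Non-empty nucleotide strings.
#' @return Identity fraction in [0, 1].
#' @examples
#' pairwise_identity("ACGT", "ACGA")  # 0.75
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  if (!is.character(seq_a) || !is.character(seq_b) ||
      length(seq_a) != 1L || length(seq_b) != 1L ||
      !nzchar(seq_a) || !nzchar(seq_b)) {
    stop("sequences must be single non-empty strings", call. = FALSE)
  }
  aln <- align_global(seq_a, seq_b)
  alen <- nchar(as.character(Biostrings::alignedPattern(aln)))
  Biostrings::nmatch(aln) / alen
}

#' Greedy OTU clustering at a fixed identity threshold
#'
#' Clones are processed in input order; each joins the first OTU whose
#' representative (founding sequence) it matches at or above `threshold`
#' identity, otherwise it founds a new OTU. Deterministic and
#' abundance-agnostic; order sensitivity is a documented property of the
#' scheme.
#'
#' @param library A [clone_library].
#' @param threshold Identity threshold in (0, 1] (default 0.99, the
#'   convention for ppk1 clone libraries).
#' @return A list of class `otu_set`; element `otus` is a list of
#'   `list(representative_id, representative, members)`, covering every clone
#'   exactly once.
#' @export
cluster_otus <- function(library, threshold = 0.99) {
  if (!inherits(library, "clone_library")) {
    stop("'library' must be a 'clone_library'", call. = FALSE)
  }
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("'threshold' must be in (0, 1]", call. = FALSE)
  }
  seqs <- library$sequences
  otus <- list()
  for (i in seq_along(seqs)) {
    placed <- FALSE
    for (k in seq_along(otus)) {
      if (pairwise_identity(seqs[[i]], otus[[k]]$representative) >=
          threshold) {
        otus[[k]]$members <- c(otus[[k]]$members, names(seqs)[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      otus[[length(otus) + 1L]] <- list(
        representative_id = names(seqs)[i],
        representative = unname(seqs[[i]]),
        members = names(seqs)[i]
      )
    }
  }
  structure(list(run_id = library$run_id, threshold = threshold, otus = otus),
            class = "otu_set")
}

#' @export
print.otu_set <- function(x, ...) {
  sizes <- vapply(x$otus, function(o) length(o$members), integer(1))
  cat(sprintf("<otu_set> %s: %d clones in %d OTUs at %.0f%% identity\n",
              x$run_id, sum(sizes), length(x$otus), 100 * x$threshold))
  invisible(x)
}

#' Construct a clade reference panel
#'
#' @param clades Character vector of clade labels from the recognized
#'   vocabulary (IA..IE, IIA..IIH, II-I).
#' @param sequences Character vector of reference nucleotide sequences,
#'   same length.
#' @return A `data.frame` of class `clade_panel` with columns `clade`,
#'   `sequence`.
#' @export
clade_panel <- function(clades, sequences) {
  if (length(clades) == 0L || length(clades) != length(sequences)) {
    stop("'clades' and 'sequences' must be non-empty and equal length",
         call. = FALSE)
  }
  bad <- !clades %in% clade_vocabulary
  if (any(bad)) {
    stop("unrecognized clade label(s): ",
         paste(unique(clades[bad]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(clades)) stop("duplicate clade labels", call. = FALSE)
  if (any(grepl("[^ACGTNacgtn]", sequences)) || any(!nzchar(sequences))) {
    stop("invalid reference sequences", call. = FALSE)
  }
  df <- data.frame(clade = clades, sequence = toupper(sequences),
                   stringsAsFactors = FALSE)
  class(df) <- c("clade_panel", "data.frame")
  df
}

#' Assign an OTU representative to an Accumulibacter clade
#'
#' The representative is compared against every panel reference by
#' [pairwise_identity]; the best-matching clade is returned if its identity
#' reaches `min_identity`, else `"unassigned"`. Exact ties on identity are
#' broken by panel order and flagged.
#'
#' @param representative Nucleotide string (an OTU representative).
#' @param panel A [clade_panel].
#' @param min_identity Minimum identity to accept an assignment
#'   (default 0.85).
#' @return A one-row `data.frame` with columns `clade`, `identity`, `tie`.
#' @export
assign_clade <- function(representative, panel, min_identity = 0.85) {
  if (!inherits(panel, "clade_panel") || nrow(panel) == 0L) {
    stop("'panel' must be a non-empty 'clade_panel'", call. = FALSE)
  }
  ids <- vapply(panel$sequence, pairwise_identity, numeric(1),
                seq_a = representative, USE.NAMES = FALSE)
  best <- which.max(ids)  # first on ties
  tie <- sum(ids == ids[best]) > 1L
  clade <- if (ids[best] >= min_identity) panel$clade[best] else "unassigned"
  data.frame(clade = clade, identity = ids[best], tie = tie,
             stringsAsFactors = FALSE)
}

#' Clade assignments for a whole library
#'
#' Clusters the library into OTUs, assigns each OTU representative to a
#' clade, and propagates the assignment to every member clone.
#'
#' @inheritParams cluster_otus
#' @param panel A [clade_panel].
#' @param min_identity Passed to [assign_clade].
#' @return Named character vector: clade label per clone id.
#' @export
assign_library <- function(library, panel, threshold = 0.99,
                           min_identity = 0.85) {
  otus <- cluster_otus(library, threshold = threshold)
  out <- character(0)
  for (o in otus$otus) {
    cl <- assign_clade(o$representative, panel,
                       min_identity = min_identity)$clade
    out[o$members] <- cl
  }
  out[names(library$sequences)]
}

#' Clade composition table for one run
#'
#' Counts clones per clade, converts to integer-rounded percentages, and sums
#' clades into Type I / Type II fractions by label prefix (an `"II*"` clade
#' belongs to Type II, any other `"I*"` clade to Type I; `"unassigned"`
#' clones are counted but excluded from type fractions).
#'
#' @param assignments Character vector of clade labels, one per clone.
#' @param run_id Run identifier.
#' @return A list of class `composition_table`: `run_id`, `counts` (named
#'   integer), `percent` (named numeric, integers summing to ~100),
#'   `type_percent` (named numeric, Type I / Type II), `n_clones`.
#' @examples
#' composition(c(rep("IA", 8), rep("IIA", 3), rep("IIB", 2)), "Run 1")
#' @export
composition <- function(assignments, run_id = "run") {
  if (length(assignments) == 0L) {
    stop("no clones to tabulate", call. = FALSE)
  }
  counts <- table(assignments)
  counts <- counts[order(names(counts))]
  n <- sum(counts)
  percent <- round(100 * as.numeric(counts) / n)
  names(percent) <- names(counts)
  is_II <- startsWith(names(counts), "II")
  is_I <- startsWith(names(counts), "I") & !is_II
  type_counts <- c("Type I" = sum(counts[is_I]), "Type II" = sum(counts[is_II]))
  n_typed <- sum(type_counts)
  type_percent <- if (n_typed > 0) round(100 * type_counts / n_typed) else
    c("Type I" = NA_real_, "Type II" = NA_real_)
  structure(
    list(run_id = run_id,
         counts = stats::setNames(as.integer(counts), names(counts)),
         percent = percent,
         type_percent = type_percent,
         n_clones = as.integer(n)),
    class = "composition_table"
  )
}

#' @export
print.composition_table <- function(x, ...) {
  cat(sprintf("<composition_table> %s (%d clones)\n", x$run_id, x$n_clones))
  tab <- data.frame(clade = names(x$counts), count = x$counts,
                    percent = x$percent, row.names = NULL)
  print(tab)
  cat(sprintf("Type I %g%% / Type II %g%%\n",
              x$type_percent[["Type I"]], x$type_percent[["Type II"]]))
  invisible(x)
}

#' Composition tables as one data.frame across runs
#'
#' @param compositions List of `composition_table` objects.
#' @return Long-format `data.frame`: `run_id`, `clade`, `count`, `percent`.
#' @export
composition_df <- function(compositions) {
  if (inherits(compositions, "composition_table")) {
    compositions <- list(compositions)
  }
  do.call(rbind, lapply(compositions, function(x) {
    data.frame(run_id = x$run_id, clade = names(x$counts),
               count = x$counts, percent = x$percent, row.names = NULL,
               stringsAsFactors = FALSE)
  }))
}
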