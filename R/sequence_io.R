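#' Construct a protein sequence collection
#'
#' A `protein_set` is the package's internal model of a collection of protein
#' sequences: a data frame with columns `id`, `description`, `residues`,
#' `name` and `species`. Ids must be unique; residues are strings over the
#' 20 canonical one-letter amino-acid codes once validated.
#'
#' @param id character vector of unique identifiers.
#' @param residues character vector of amino-acid strings (one per id).
#' @param description free-text descriptions (recycled; default `""`).
#' @param name optional protein names used for species-grouping during dataset
#'   construction; defaults to `id`.
#' @param species optional species tags.
#' @return A data frame of class `protein_set`.
#' @export
#' @examples
#' ps <- protein_set(c("P1", "P2"), c("AEAA", "MKLV"))
protein_set <- function(id, residues, description = "", name = id,
                        species = NA_character_) {
  id <- as.character(id)
  residues <- as.character(residues)
  if (length(id) != length(residues))
    stopf("id and residues must have equal length")
  if (anyDuplicated(id))
    stopf("duplicate protein ids: %s",
          paste(unique(id[duplicated(id)]), collapse = ", "))
  if (any(!nzchar(residues)))
    stopf("empty residue string for id(s): %s",
          paste(id[!nzchar(residues)], collapse = ", "))
  out <- data.frame(id = id,
                    description = rep_len(as.character(description), length(id)),
                    residues = residues,
                    name = rep_len(as.character(name), length(id)),
                    species = rep_len(as.character(species), length(id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("protein_set", "data.frame")
  out
}

#' Read protein sequences from a FASTA file
#'
#' Parsing is backed by [Biostrings::readAAStringSet()]. The header token
#' before the first whitespace becomes the id; the remainder becomes the
#' description. Records with an empty sequence are rejected with the line of
#' the offending header.
#'
#' @param path path to a (multi-record) FASTA file; wrapped or unwrapped lines.
#' @return A [protein_set] in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stopf("empty FASTA file: %s", path)
  if (!startsWith(first, ">"))
    stopf("malformed FASTA (line 1 does not start with '>'): %s", path)
  set <- Biostrings::readAAStringSet(path)
  widths <- Biostrings::width(set)
  if (any(widths == 0L)) {
    # locate the header line of the first empty record for the error message
    bad <- which(widths == 0L)[1L]
    lines <- readLines(path)
    hdr_lines <- which(startsWith(lines, ">"))
    stopf("malformed FASTA: record %d (line %d) has an empty sequence",
          bad, hdr_lines[bad])
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  protein_set(id = ids, residues = as.character(set), description = desc)
}

#' Write a protein collection to FASTA
#'
#' @param proteins a [protein_set].
#' @param path output file path.
#' @param width line-wrap width for residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  set <- Biostrings::AAStringSet(setNames(proteins$residues, proteins$id))
  hdr <- ifelse(nzchar(proteins$description),
                paste(proteins$id, proteins$description), proteins$id)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Validate residue strings against the canonical amino-acid alphabet
#'
#' Lowercase residues are uppercased first. Non-canonical characters
#' (ambiguity codes B/Z/X, selenocysteine U, pyrrolysine O, stops, gaps) are
#' handled according to `policy`: `"reject"` raises an error; `"drop_residue"`
#' removes them (a message reports the count). A sequence that becomes empty
#' after cleaning is an error. The operation is idempotent.
#'
#' @param x a [protein_set] or a single residue string.
#' @param policy `"drop_residue"` (default) or `"reject"`.
#' @return The validated object, same type as `x`.
#' @export
validate_sequence <- function(x, policy = c("drop_residue", "reject")) {
  policy <- match.arg(policy)
  if (inherits(x, "protein_set")) {
    cleaned <- vapply(seq_len(nrow(x)), function(i)
      validate_residues(x$residues[i], policy, x$id[i]), character(1))
    x$residues <- cleaned
    return(x)
  }
  validate_residues(as.character(x), policy, "<sequence>")
}

validate_residues <- function(res, policy, id) {
  res <- toupper(res)
  chars <- strsplit(res, "", fixed = TRUE)[[1]]
  bad <- !(chars %in% AA_ALPHABET)
  if (any(bad)) {
    if (policy == "reject")
      stopf("sequence %s contains %d non-canonical residue(s): %s",
            id, sum(bad), paste(unique(chars[bad]), collapse = " "))
    message(sprintf("validate_sequence: dropped %d non-canonical residue(s) from %s",
                    sum(bad), id))
    chars <- chars[!bad]
  }
  if (length(chars) == 0L)
    stopf("sequence %s is empty after removing non-canonical residues", id)
  paste(chars, collapse = "")
}

#' Read protein-to-family annotations
#'
#' Expects two-column delimited text (`protein_id`, `family_id`), tab- or
#' whitespace-separated, with an optional header row. Duplicate pairs are
#' collapsed (a message reports the count).
#'
#' @param path path to the annotation table.
#' @return A data frame with columns `protein_id` and `family_id`; zero rows
#'   for an empty file.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(protein_id = character(0), family_id = character(0),
                      stringsAsFactors = FALSE))
  fields <- strsplit(lines, "[\t ]+")
  n_fields <- lengths(fields)
  if (any(n_fields < 2L))
    stopf("annotation row %d has fewer than 2 columns: '%s'",
          which(n_fields < 2L)[1L], lines[which(n_fields < 2L)[1L]])
  df <- data.frame(protein_id = vapply(fields, `[`, "", 1L),
                   family_id = vapply(fields, `[`, "", 2L),
                   stringsAsFactors = FALSE)
  if (tolower(df$protein_id[1]) %in% c("protein_id", "protein") &&
      tolower(df$family_id[1]) %in% c("family_id", "family"))
    df <- df[-1L, , drop = FALSE]
  ndup <- sum(duplicated(df))
  if (ndup > 0L) {
    message(sprintf("read_annotations: collapsed %d duplicate pair(s)", ndup))
    df <- df[!duplicated(df), , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Write protein-to-family annotations as TSV
#'
#' @param annotations data frame with columns `protein_id`, `family_id`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  write.table(annotations[, c("protein_id", "family_id")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
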