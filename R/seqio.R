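#' Sequence record constructor
#'
#' A lightweight container for one input sequence: the header token (`id`),
#' the remainder of the header (`description`), the normalized residues
#' (uppercase, no whitespace) and their count.
#'
#' @param id Header token (non-empty string).
#' @param residues Character string of residues; normalized with
#'   [sanitize()] under the permissive policy.
#' @param description Remainder of the FASTA header, default `""`.
#' @return An object of class `sequence_record` with fields `id`,
#'   `description`, `residues`, `length`.
#' @export
sequence_record <- function(id, residues, description = "") {
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id))
    abort_format("sequence record id must be a non-empty string")
  residues <- sanitize(residues, policy = "permissive")
  structure(
    list(id = id, description = description, residues = residues,
         length = nchar(residues)),
    class = "sequence_record"
  )
}

#' @export
print.sequence_record <- function(x, ...) {
  head <- if (x$length > 60L) paste0(substr(x$residues, 1L, 57L), "...")
          else x$residues
  cat(sprintf("<sequence_record> %s (%d residues)\n  %s\n", x$id, x$length, head))
  invisible(x)
}

#' Read sequences from a FASTA file
#'
#' Parses a (multi-line) FASTA file into a list of [sequence_record()]s in
#' file order. Sequence lines are concatenated, whitespace is stripped and
#' residues are uppercased; the first whitespace-delimited token of each
#' header is the record id, the remainder its description.
#'
#' @param path Path to an existing FASTA file.
#' @return List of `sequence_record` objects, one per `>` header.
#' @export
read_fasta <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    abort_io("path must be a single file name")
  if (!file.exists(path))
    abort_io(sprintf("FASTA file not found: '%s'", path))
  # reject content before the first header up front (Biostrings also errors,
  # but with a parser-internal message)
  first <- ""
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) break
    if (nzchar(trimws(line))) { first <- trimws(line); break }
  }
  if (nzchar(first) && !startsWith(first, ">"))
    abort_format("malformed FASTA: content before the first '>' header")
  seqs <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) abort_format(paste0("malformed FASTA: ", conditionMessage(e)))
  )
  headers <- names(seqs)
  lapply(seq_along(seqs), function(i) {
    h <- trimws(headers[i])
    if (!nzchar(h))
      abort_format(sprintf("record %d has an empty id", i))
    id <- sub("[[:space:]].*$", "", h)
    desc <- trimws(sub("^[^[:space:]]+", "", h))
    sequence_record(id = id, residues = as.character(seqs[[i]]),
                    description = desc)
  })
}

#' Write sequence records to a FASTA file
#'
#' @param records A `sequence_record` or list of them.
#' @param path Output file path.
#' @param width Residues per line, default 60.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (inherits(records, "sequence_record")) records <- list(records)
  if (!all(vapply(records, inherits, logical(1), "sequence_record")))
    abort_contract("records must be sequence_record objects")
  dir <- dirname(path)
  if (!dir.exists(dir)) abort_io(sprintf("directory does not exist: '%s'", dir))
  x <- Biostrings::BStringSet(vapply(records, `[[`, character(1), "residues"))
  names(x) <- vapply(records, function(r) {
    if (nzchar(r$description)) paste(r$id, r$description) else r$id
  }, character(1))
  tryCatch(
    Biostrings::writeXStringSet(x, filepath = path, format = "fasta",
                                width = as.integer(width)),
    error = function(e) abort_io(conditionMessage(e))
  )
  invisible(path)
}

#' Normalize a raw residue string
#'
#' Folds lowercase to uppercase and removes all whitespace. Under the
#' `strict` policy every remaining character must be one of `A`, `C`, `G`,
#' `T`; the `permissive` policy (the default elsewhere in the package)
#' retains any non-whitespace character, since the LCS algorithms are
#' alphabet-agnostic.
#'
#' @param raw Character string.
#' @param policy `"permissive"` or `"strict"`.
#' @return Normalized character string.
#' @export
sanitize <- function(raw, policy = c("permissive", "strict")) {
  policy <- match.arg(policy)
  if (!is.character(raw) || length(raw) != 1L || is.na(raw))
    abort_contract("raw must be a single character string")
  out <- toupper(gsub("[[:space:]]+", "", raw))
  if (policy == "strict" && nzchar(out)) {
    chars <- strsplit(out, "", fixed = TRUE)[[1]]
    bad <- which(!chars %in% c("A", "C", "G", "T"))
    if (length(bad) > 0L)
      abort_validation(sprintf(
        "invalid residue '%s' at position %d under strict policy",
        chars[bad[1]], bad[1]))
  }
  out
}

#' Build the joint alphabet of two sequences
#'
#' The alphabet C is the deduplicated union of the characters of `A` and
#' `B`, sorted ascending by character code so that occurrence tables are
#' reproducible across runs. Each character's rank `c` is its 1-based
#' position in C.
#'
#' @param A,B Character strings (either may be empty).
#' @return An object of class `lcs_alphabet` with fields `symbols` (single
#'   string), `chars` (character vector) and `rank` (named integer vector).
#' @export
build_alphabet <- function(A, B) {
  if (!is.character(A) || length(A) != 1L || !is.character(B) || length(B) != 1L)
    abort_contract("A and B must be single character strings")
  joint <- paste0(A, B)
  codes <- if (nzchar(joint)) sort(unique(utf8ToInt(joint))) else integer(0)
  chars <- if (length(codes)) vapply(codes, intToUtf8, character(1)) else character(0)
  structure(
    list(symbols = paste(chars, collapse = ""),
         chars = chars,
         rank = setNames(seq_along(chars), chars)),
    class = "lcs_alphabet"
  )
}

#' @export
print.lcs_alphabet <- function(x, ...) {
  cat(sprintf("<lcs_alphabet> %d symbols: \"%s\"\n", length(x$chars), x$symbols))
  invisible(x)
}

#' Rank of a character in an alphabet
#'
#' @param alphabet An `lcs_alphabet`.
#' @param char Single character.
#' @return Its 1-based rank in `alphabet$symbols`.
#' @export
alphabet_rank <- function(alphabet, char) {
  if (!inherits(alphabet, "lcs_alphabet"))
    abort_contract("alphabet must be an lcs_alphabet")
  r <- alphabet$rank[char]
  if (is.na(r))
    abort_contract(sprintf("character '%s' has no rank in the alphabet", char))
  unname(r)
}
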