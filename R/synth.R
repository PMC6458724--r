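# seeded RNG scoping: all synthetic generation runs under an explicitly named
# generator (Mersenne-Twister + Rejection sampling) so fixtures are
# reproducible across R versions and platforms, and the caller's RNG state is
# untouched
with_seeded_rng <- function(seed, code) {
  if (!is_count(abs(seed), min = 0L)) abort_contract("seed must be an integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

#' Generate a uniformly random DNA sequence
#'
#' Emulates a random DNA sequence generator: residues are drawn
#' independently and uniformly from the alphabet. Deterministic given
#' `(length, seed, alphabet)` — the generator kind is pinned explicitly so
#' the same spec reproduces byte-identical output across platforms.
#'
#' @param length Number of residues (>= 0).
#' @param seed Integer seed.
#' @param alphabet Character string of symbols to draw from; default
#'   `"ACGT"`. Must be non-empty when `length > 0`.
#' @param id Record id; a descriptive default is derived from the arguments.
#' @return A [sequence_record()].
#' @export
generate_dna <- function(length, seed, alphabet = "ACGT",
                         id = sprintf("synth_len%d_seed%d", length, seed)) {
  if (!is_count(length, min = 0L))
    abort_contract("length must be a nonnegative integer")
  if (length > 0L && (!is.character(alphabet) || !nzchar(alphabet)))
    abort_contract("alphabet must be non-empty when length > 0")
  chars <- strsplit(alphabet, "", fixed = TRUE)[[1]]
  residues <- if (length == 0L) "" else with_seeded_rng(seed, {
    paste(sample(chars, length, replace = TRUE), collapse = "")
  })
  rec <- sequence_record(id = id, residues = residues,
                         description = sprintf("uniform random, alphabet %s",
                                               toupper(alphabet)))
  rec
}

#' Specification of a synthetic sequence pair
#'
#' Bundles the parameters of one reproducible synthetic pair: the two
#' lengths, the alphabet, the seed, and the length of a common subsequence
#' to plant in both sequences.
#'
#' @param length_a,length_b Positive integer lengths (bases).
#' @param plant_length Length of the planted common subsequence,
#'   `0 <= plant_length <= min(length_a, length_b)`.
#' @param alphabet Symbols, default `"ACGT"`.
#' @param seed Integer seed.
#' @return Object of class `synthetic_pair_spec`.
#' @export
synthetic_pair_spec <- function(length_a, length_b, plant_length = 0L,
                                alphabet = "ACGT", seed = 1L) {
  if (!is_count(length_a, min = 1L) || !is_count(length_b, min = 1L))
    abort_contract("length_a and length_b must be positive integers")
  if (!is_count(plant_length, min = 0L))
    abort_contract("plant_length must be a nonnegative integer")
  if (plant_length > min(length_a, length_b))
    abort_contract("plant_length must not exceed min(length_a, length_b)")
  if (!is.character(alphabet) || !nzchar(alphabet))
    abort_contract("alphabet must be a non-empty string")
  structure(
    list(length_a = as.integer(length_a), length_b = as.integer(length_b),
         plant_length = as.integer(plant_length), alphabet = alphabet,
         seed = as.integer(seed)),
    class = "synthetic_pair_spec"
  )
}

#' Generate a sequence pair with a planted common subsequence
#'
#' Draws one random string of length `plant_length` and embeds it, in order
#' but not necessarily contiguously, into both output sequences: the plant
#' positions within each sequence are a sorted sample without replacement,
#' all remaining positions are filled uniformly at random. The planted
#' string is by construction a common subsequence, so
#' `lcs_length(A, B) >= plant_length` — a provable lower bound for tests.
#'
#' @param spec A [synthetic_pair_spec()].
#' @return List with elements `a`, `b` (the two [sequence_record()]s) and
#'   `lower_bound` (= `plant_length`).
#' @export
generate_planted_pair <- function(spec) {
  if (!inherits(spec, "synthetic_pair_spec"))
    abort_contract("spec must be a synthetic_pair_spec")
  chars <- strsplit(spec$alphabet, "", fixed = TRUE)[[1]]
  out <- with_seeded_rng(spec$seed, {
    plant <- if (spec$plant_length > 0L)
      sample(chars, spec$plant_length, replace = TRUE) else character(0)
    embed <- function(len) {
      res <- sample(chars, len, replace = TRUE)
      if (spec$plant_length > 0L) {
        pos <- sort(sample.int(len, spec$plant_length))
        res[pos] <- plant
      }
      paste(res, collapse = "")
    }
    list(a = embed(spec$length_a), b = embed(spec$length_b))
  })
  list(
    a = sequence_record(sprintf("planted_a_seed%d", spec$seed), out$a,
                        description = sprintf("plant_length=%d", spec$plant_length)),
    b = sequence_record(sprintf("planted_b_seed%d", spec$seed), out$b,
                        description = sprintf("plant_length=%d", spec$plant_length)),
    lower_bound = spec$plant_length
  )
}
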