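#' Synthesize a CDEII-like sequence with controlled run content
#'
#' Constructs a random DNA sequence of given length whose A+T fraction and
#' homopolymeric A/T run content (fraction of bp inside single-base A or T
#' runs of length >= 4, see [run_fraction()]) match a [sequence_spec()].  This
#' emulates the randomized-CDEII synthetic centromere libraries used to probe
#' the role of run content in centromere function: composition is held fixed
#' while run content is dialed.
#'
#' The construction is exact-by-design: `round(target_run_fraction * length)`
#' bp are laid down as homopolymer blocks of length 4-8 (matching the
#' observation that natural CDEII elements contain no runs beyond 8), base
#' alternating between A and T so adjacent blocks never merge; remaining A/T
#' and G/C bp are interleaved with a greedy assignment that never creates an
#' unplanned run of 4 nor extends a block.  The result is verified against
#' [run_stats()] and the construction errors if the spec is infeasible (e.g.
#' `0 < round(target_run_fraction * length) < 4`).
#'
#' @param spec a [sequence_spec()].
#' @return A single uppercase DNA string; deterministic given `spec$seed`.
#'   Its A+T fraction is within 0.02 of `at_fraction` and its run fraction
#'   within 0.05 of `target_run_fraction`.
#' @examples
#' s <- generate_cdeii_sequence(sequence_spec(84, 0.9, 0.5, seed = 7))
#' run_fraction(s)
#' @export
generate_cdeii_sequence <- function(spec) {
  stopifnot(inherits(spec, "sequence_spec"))
  L <- spec$length
  n_at <- round(spec$at_fraction * L)
  n_gc <- L - n_at
  n_run <- round(spec$target_run_fraction * L)
  if (n_run > n_at) stop("target_run_fraction exceeds at_fraction")
  if (n_run > 0 && n_run < 4)
    stop("infeasible: target run content below one minimal run of 4 bp")
  set.seed(spec$seed)
  for (attempt in 1:50) {
    seqc <- try(build_cdeii(L, n_at, n_gc, n_run), silent = TRUE)
    if (inherits(seqc, "try-error")) next
    st <- run_stats(seqc)
    if (abs(st$at_fraction - spec$at_fraction) <= 0.02 &&
        abs(st$run_fraction - spec$target_run_fraction) <= 0.05)
      return(seqc)
  }
  stop("could not realize the requested composition; spec may be infeasible")
}

## One construction attempt; uses the caller's RNG stream.
build_cdeii <- function(L, n_at, n_gc, n_run) {
  ## homopolymer blocks of 4..8 bp summing exactly to n_run
  sizes <- integer(0)
  rem <- n_run
  while (rem > 0) {
    cand <- 4:min(8, rem)
    cand <- cand[rem - cand == 0 | rem - cand >= 4]
    if (!length(cand)) stop("block decomposition failed")
    s <- if (length(cand) == 1) cand else sample(cand, 1)
    sizes <- c(sizes, s)
    rem <- rem - s
  }
  nb <- length(sizes)
  bases <- rep(c("A", "T"), length.out = nb)
  if (nb && stats::runif(1) < 0.5) bases <- rev(rep(c("T", "A"), length.out = nb))

  ## filler template: W = A/T to be assigned, S = G/C
  n_free <- n_at - n_run
  filler <- sample(c(rep("W", n_free), rep("S", n_gc)))
  ## split the filler into nb + 1 chunks (possibly empty) and interleave
  m <- length(filler)
  cuts <- sort(sample.int(m + 1, nb, replace = TRUE) - 1L)
  template <- character(0)
  block_of <- integer(0)   # 0 = filler, i = block i
  prev <- 0L
  for (i in seq_len(nb)) {
    chunk <- if (cuts[i] > prev) filler[(prev + 1):cuts[i]] else character(0)
    template <- c(template, chunk, rep(bases[i], sizes[i]))
    block_of <- c(block_of, rep(0L, length(chunk)), rep(i, sizes[i]))
    prev <- cuts[i]
  }
  if (prev < m) {
    template <- c(template, filler[(prev + 1):m])
    block_of <- c(block_of, rep(0L, m - prev))
  }

  ## greedy left-to-right assignment of W (A/T) and S (G/C):
  ## never create an A or T run of 4 outside blocks, never extend a block
  out <- character(L)
  run_base <- ""
  run_len <- 0L
  for (i in seq_len(L)) {
    ch <- template[i]
    if (ch %in% c("A", "T", "G", "C")) {
      out[i] <- ch
    } else if (ch == "S") {
      out[i] <- sample(c("G", "C"), 1)
    } else {
      choices <- c("A", "T")
      if (run_base %in% choices && run_len >= 3)
        choices <- setdiff(choices, run_base)
      nxt <- if (i < L && block_of[i + 1] > 0) template[i + 1] else ""
      if (nxt %in% choices) choices <- setdiff(choices, nxt)
      if (!length(choices)) stop("greedy assignment stuck")
      out[i] <- if (length(choices) == 1) choices else sample(choices, 1)
    }
    if (out[i] == run_base) run_len <- run_len + 1L
    else { run_base <- out[i]; run_len <- 1L }
  }
  paste(out, collapse = "")
}

#' Write sequences to FASTA
#'
#' Thin wrapper over `Biostrings::writeXStringSet` for character vectors.
#'
#' @param sequences named character vector of DNA strings.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
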