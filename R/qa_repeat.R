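#' Configuration for locating the RUNX2 Q/A repeat domain
#'
#' The glutamine/alanine (Q/A) tandem-repeat domain of RUNX2 sits between
#' conserved stretches of the protein. Those stretches act as reference
#' markers: a sequence is only screened in when both flanking anchors are
#' found, mirroring the exclusion rule applied to raw amplicons. The anchor
#' motifs themselves are configuration, not data: the defaults are the
#' `MRIPV` N-terminal start of the RUNX P2-promoter isoform (5') and the
#' conserved `PSTSR` motif downstream of the repeat region (3'). Every
#' extraction records the anchors used in its audit so a run is reproducible.
#'
#' @param five_prime_anchor Amino-acid motif expected upstream of the repeat.
#' @param three_prime_anchor Amino-acid motif expected downstream of the repeat.
#' @param max_anchor_mismatches Number of substitutions tolerated when
#'   matching each anchor (Hamming distance; no indels).
#' @param min_run_length Minimum length for a polyQ or polyA run to count as
#'   a repeat tract. Must be at least 3.
#' @param max_interruptions Number of non-target residues tolerated inside a
#'   run. The default 0 counts only pure contiguous ("in tandem") runs;
#'   interruption tolerance is opt-in because real RUNX2 polyQ tracts can be
#'   interrupted. Interrupting residues never count toward the run length.
#' @return A list of class `repeat_config`.
#' @examples
#' cfg <- repeat_config()
#' locate_qa_domain("MRIPVQQQQQAAAPSTSR", cfg)
#' @export
repeat_config <- function(five_prime_anchor = "MRIPV",
                          three_prime_anchor = "PSTSR",
                          max_anchor_mismatches = 0L,
                          min_run_length = 3L,
                          max_interruptions = 0L) {
  five_prime_anchor <- toupper(five_prime_anchor)
  three_prime_anchor <- toupper(three_prime_anchor)
  if (!nzchar(five_prime_anchor) || !nzchar(three_prime_anchor))
    stop("anchor motifs must be non-empty")
  if (max_anchor_mismatches < 0) stop("max_anchor_mismatches must be >= 0")
  if (min_run_length < 3) stop("min_run_length must be >= 3")
  if (max_interruptions < 0) stop("max_interruptions must be >= 0")
  # anchors containing long Q or A runs would be indistinguishable from the
  # repeat tract they are meant to delimit
  run_re <- function(ch) sprintf("%s{%d,}", ch, min_run_length + 1L)
  for (a in c(five_prime_anchor, three_prime_anchor)) {
    if (grepl(run_re("Q"), a) || grepl(run_re("A"), a))
      stop("anchors must not contain Q or A runs longer than min_run_length")
  }
  structure(list(five_prime_anchor = five_prime_anchor,
                 three_prime_anchor = three_prime_anchor,
                 max_anchor_mismatches = as.integer(max_anchor_mismatches),
                 min_run_length = as.integer(min_run_length),
                 max_interruptions = as.integer(max_interruptions)),
            class = "repeat_config")
}

#' Translate a coding nucleotide sequence
#'
#' Standard genetic-code translation of an amplicon in a given reading frame.
#' Codons containing an ambiguity (`N`) translate to `X`; a trailing partial
#' codon is dropped. Internal stop codons are not fatal (the downstream
#' anchor screen decides whether the sequence is usable); their presence is
#' flagged in the `internal_stop` attribute of the result.
#'
#' @param nt_sequence A DNA string (A/C/G/T/N, case-insensitive).
#' @param frame Reading-frame offset, 0, 1 or 2.
#' @return The amino-acid sequence as a character scalar, with attribute
#'   `internal_stop` (logical).
#' @examples
#' translate_cds("CAGCAGGCT")     # "QQA"
#' translate_cds("ACAGCAGGCT", 1) # frame shift
#' @export
translate_cds <- function(nt_sequence, frame = 0L) {
  if (length(nt_sequence) != 1L || !nzchar(nt_sequence))
    stop("nt_sequence must be a single non-empty string")
  if (!frame %in% 0:2) stop("frame must be 0, 1 or 2")
  s <- toupper(nt_sequence)
  if (grepl("[^ACGTN]", s)) stop("alphabet must be A/C/G/T/N")
  s <- substr(s, frame + 1L, nchar(s))
  if (nchar(s) < 3L) stop("sequence shorter than one codon after frame offset")
  s <- substr(s, 1L, (nchar(s) %/% 3L) * 3L)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(s),
                                           if.fuzzy.codon = "X"))
  structure(aa, internal_stop = grepl("\\*(?!$)", aa, perl = TRUE))
}

# Hamming-tolerant anchor search; returns 1-based start positions.
match_anchor <- function(aa_sequence, anchor, max_mismatch) {
  hits <- Biostrings::matchPattern(anchor, Biostrings::AAString(aa_sequence),
                                   max.mismatch = max_mismatch,
                                   with.indels = FALSE)
  Biostrings::start(hits)
}

#' Locate the Q/A repeat domain between conserved anchors
#'
#' Finds the interval strictly between the end of the 5' anchor match and the
#' start of the 3' anchor match. Anchor matching tolerates up to
#' `cfg$max_anchor_mismatches` substitutions. A sequence in which either
#' anchor is absent fails the screen (returned, not raised, so that batch
#' extraction can tabulate failures). If several matches exist, the leftmost
#' 5' match and the rightmost 3' match compatible with it are used, with a
#' warning.
#'
#' @param aa_sequence Amino-acid sequence (character scalar).
#' @param cfg A [repeat_config()].
#' @return A list with `passed` (logical), `domain_start`, `domain_end`
#'   (0-based half-open coordinates on the amino-acid sequence) and `reason`
#'   (`NA` when passed).
#' @export
locate_qa_domain <- function(aa_sequence, cfg = repeat_config()) {
  stopifnot(inherits(cfg, "repeat_config"))
  aa_sequence <- toupper(aa_sequence)
  if (nchar(aa_sequence) <=
      nchar(cfg$five_prime_anchor) + nchar(cfg$three_prime_anchor))
    return(list(passed = FALSE, domain_start = NA_integer_,
                domain_end = NA_integer_, reason = "sequence shorter than anchors"))
  s5 <- match_anchor(aa_sequence, cfg$five_prime_anchor, cfg$max_anchor_mismatches)
  s3 <- match_anchor(aa_sequence, cfg$three_prime_anchor, cfg$max_anchor_mismatches)
  if (length(s5) == 0L)
    return(list(passed = FALSE, domain_start = NA_integer_,
                domain_end = NA_integer_, reason = "5' anchor not found"))
  if (length(s3) == 0L)
    return(list(passed = FALSE, domain_start = NA_integer_,
                domain_end = NA_integer_, reason = "3' anchor not found"))
  if (length(s5) > 1L || length(s3) > 1L)
    warning("multiple anchor matches; using leftmost 5' and rightmost compatible 3'")
  p5 <- min(s5)
  end5 <- p5 + nchar(cfg$five_prime_anchor) - 1L        # 1-based inclusive end
  s3_ok <- s3[s3 > end5]
  if (length(s3_ok) == 0L)
    stop("malformed sequence: 3' anchor precedes the 5' anchor")
  p3 <- max(s3_ok)
  # 0-based half-open: [end of 5' anchor, start of 3' anchor)
  list(passed = TRUE, domain_start = end5, domain_end = p3 - 1L, reason = NA_character_)
}

# Best run of `target` within residues `chars`, allowing up to `max_int`
# interior non-target residues (which do not count toward the run). Returns
# count and 1-based start/end; count 0 when the residue is absent.
best_run <- function(chars, target, max_int) {
  pos <- which(chars == target)
  if (length(pos) == 0L) return(list(count = 0L, start = NA_integer_, end = NA_integer_))
  best <- list(count = 0L, start = NA_integer_, end = NA_integer_)
  a <- 1L
  for (b in seq_along(pos)) {
    while ((pos[b] - pos[a] + 1L) - (b - a + 1L) > max_int) a <- a + 1L
    cnt <- b - a + 1L
    if (cnt > best$count) best <- list(count = cnt, start = pos[a], end = pos[b])
  }
  best
}

#' Count the tandem glutamine and alanine runs within a domain
#'
#' Within the located Q/A domain, the polyQ count is the number of glutamines
#' in the maximal glutamine run (allowing at most `cfg$max_interruptions`
#' interior non-Q residues, which do not count), and likewise for polyA. The
#' reported polyQ run must start before the polyA run; a domain whose polyA
#' tract precedes its polyQ tract is malformed and raises an error.
#'
#' @param aa_sequence Amino-acid sequence.
#' @param span Integer vector `c(start, end)`, 0-based half-open.
#' @param cfg A [repeat_config()].
#' @return A list with `passed`; when passed, integer `q_count`, `a_count`
#'   and 0-based half-open run coordinates `q_start`, `q_end`, `a_start`,
#'   `a_end` on the full sequence.
#' @examples
#' count_tandem_repeats("QQQQQAAA", c(0, 8))
#' @export
count_tandem_repeats <- function(aa_sequence, span, cfg = repeat_config()) {
  stopifnot(inherits(cfg, "repeat_config"), length(span) == 2L)
  n <- nchar(aa_sequence)
  if (span[1] < 0 || span[2] > n || span[1] >= span[2])
    stop("span out of sequence bounds")
  region <- substr(toupper(aa_sequence), span[1] + 1L, span[2])
  chars <- strsplit(region, "", fixed = TRUE)[[1]]
  q <- best_run(chars, "Q", cfg$max_interruptions)
  a_all <- best_run(chars, "A", cfg$max_interruptions)
  fail <- function(reason) list(passed = FALSE, reason = reason)
  if (q$count < cfg$min_run_length) {
    if (a_all$count >= cfg$min_run_length) return(fail("no polyQ run of minimum length"))
    return(fail("no polyQ or polyA run of minimum length"))
  }
  # polyA must start after the end of the chosen polyQ run
  a <- best_run(replace(chars, seq_len(q$end), "."), "A", cfg$max_interruptions)
  if (a$count < cfg$min_run_length) {
    if (a_all$count >= cfg$min_run_length && !is.na(a_all$start) && a_all$start < q$start)
      stop("malformed domain: polyA run precedes polyQ run")
    return(fail("no polyA run of minimum length after the polyQ run"))
  }
  list(passed = TRUE,
       q_count = q$count, a_count = a$count,
       q_start = span[1] + q$start - 1L, q_end = span[1] + q$end,
       a_start = span[1] + a$start - 1L, a_end = span[1] + a$end,
       reason = NA_character_)
}

#' Glutamine/alanine repeat ratio
#'
#' The number of tandem glutamine residues divided by the number of tandem
#' alanine residues.
#'
#' @param q_count Non-negative integer polyQ count.
#' @param a_count Positive integer polyA count.
#' @return `q_count / a_count`.
#' @examples
#' qa_ratio(21, 9)  # 2.33...
#' @export
qa_ratio <- function(q_count, a_count) {
  if (any(a_count < 1)) stop("a_count must be >= 1")
  if (any(q_count < 0)) stop("q_count must be >= 0")
  q_count / a_count
}

extract_one <- function(aa, cfg) {
  loc <- locate_qa_domain(aa, cfg)
  if (!loc$passed)
    return(list(passed = FALSE, reason = loc$reason))
  cnt <- count_tandem_repeats(aa, c(loc$domain_start, loc$domain_end), cfg)
  if (!cnt$passed)
    return(list(passed = FALSE, reason = cnt$reason,
                domain_start = loc$domain_start, domain_end = loc$domain_end))
  list(passed = TRUE, q_count = cnt$q_count, a_count = cnt$a_count,
       qa_ratio = qa_ratio(cnt$q_count, cnt$a_count),
       domain_start = loc$domain_start, domain_end = loc$domain_end,
       reason = NA_character_)
}

#' Extract Q/A repeat calls from a set of sequences
#'
#' Runs the full screen-locate-count pipeline on a FASTA file or a
#' `Biostrings` string set. Nucleotide input is translated in all three
#' reading frames; the frame in which both anchors are found wins, ties
#' broken by the lowest frame index. Record IDs are taken as species IDs.
#'
#' @param sequences Path to a FASTA file, an `AAStringSet`/`DNAStringSet`,
#'   or a named character vector of sequences.
#' @param cfg A [repeat_config()].
#' @param input_type `"auto"` (detect from alphabet), `"protein"` or
#'   `"nucleotide"`.
#' @return A data.frame with one row per record: `species_id`, `q_count`,
#'   `a_count`, `qa_ratio`, `passed_screen`, `domain_start`, `domain_end`,
#'   `frame` (NA for protein input), `reason`. The anchor configuration and
#'   per-record match details are attached as the `"audit"` attribute
#'   (serializable to JSON).
#' @export
extract_qa <- function(sequences, cfg = repeat_config(),
                       input_type = c("auto", "protein", "nucleotide")) {
  input_type <- match.arg(input_type)
  seqs <- as_named_sequences(sequences, input_type)
  input_type <- attr(seqs, "input_type")
  rows <- vector("list", length(seqs))
  audit <- list(config = unclass(cfg), records = list())
  for (i in seq_along(seqs)) {
    id <- names(seqs)[i]
    if (identical(input_type, "nucleotide")) {
      res <- list(passed = FALSE, reason = "no frame with both anchors")
      frame_used <- NA_integer_
      for (f in 0:2) {
        aa <- tryCatch(translate_cds(seqs[[i]], f), error = function(e) NULL)
        if (is.null(aa)) next
        r <- extract_one(as.character(aa), cfg)
        if (r$passed) { res <- r; frame_used <- f; break }
      }
    } else {
      res <- extract_one(seqs[[i]], cfg)
      frame_used <- NA_integer_
    }
    rows[[i]] <- data.frame(
      species_id = id,
      q_count = if (res$passed) res$q_count else NA_integer_,
      a_count = if (res$passed) res$a_count else NA_integer_,
      qa_ratio = if (res$passed) res$qa_ratio else NA_real_,
      passed_screen = res$passed,
      domain_start = if (!is.null(res$domain_start)) res$domain_start else NA_integer_,
      domain_end = if (!is.null(res$domain_end)) res$domain_end else NA_integer_,
      frame = frame_used,
      reason = res$reason,
      stringsAsFactors = FALSE)
    audit$records[[id]] <- list(passed = res$passed, reason = res$reason,
                                frame = frame_used)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "audit") <- audit
  out
}

# Normalize the accepted input forms of extract_qa to a named character
# vector with an "input_type" attribute.
as_named_sequences <- function(sequences, input_type) {
  if (inherits(sequences, "AAStringSet")) {
    v <- as.character(sequences); input_type <- "protein"
  } else if (inherits(sequences, "DNAStringSet")) {
    v <- as.character(sequences); input_type <- "nucleotide"
  } else if (is.character(sequences) && length(sequences) == 1L &&
             file.exists(sequences)) {
    ss <- Biostrings::readBStringSet(sequences)
    v <- toupper(as.character(ss))
    names(v) <- sub("\\s.*$", "", names(ss))
  } else if (is.character(sequences)) {
    if (is.null(names(sequences))) stop("sequences must be named")
    v <- toupper(sequences)
  } else stop("unsupported sequence input")
  if (identical(input_type, "auto")) {
    input_type <- if (all(grepl("^[ACGTN]+$", v))) "nucleotide" else "protein"
  }
  structure(v, input_type = input_type)
}
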