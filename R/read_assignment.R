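#' Read single-end short reads from FASTQ
#'
#' @param path FASTQ path (uncompressed or gzipped).
#' @return A `data.frame` with columns `read_id` and `sequence` (uppercase).
#' @export
read_fastq <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = sub("[[:space:]].*$", "", names(seqs)),
             sequence = toupper(as.character(seqs)),
             stringsAsFactors = FALSE, row.names = NULL)
}

.as_reads <- function(reads) {
  if (is.data.frame(reads)) {
    stopifnot(all(c("read_id", "sequence") %in% names(reads)))
    data.frame(read_id = as.character(reads$read_id),
               sequence = toupper(as.character(reads$sequence)),
               stringsAsFactors = FALSE)
  } else if (is.character(reads)) {
    if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
    data.frame(read_id = names(reads), sequence = toupper(unname(reads)),
               stringsAsFactors = FALSE)
  } else stop("reads must be a data.frame(read_id, sequence) or named character vector")
}

.as_targets <- function(targets) {
  if (inherits(targets, "RepeatAssembly")) return(targets$records)
  if (methods::is(targets, "DNAStringSet")) return(targets)
  if (is.character(targets) && !is.null(names(targets))) {
    return(Biostrings::DNAStringSet(toupper(targets)))
  }
  if (is.character(targets) && length(targets) == 1L && file.exists(targets)) {
    g <- Biostrings::readDNAStringSet(targets)
    names(g) <- sub("[[:space:]].*$", "", names(g))
    return(g)
  }
  stop("targets must be a RepeatAssembly, DNAStringSet, named character vector or FASTA path")
}

.empty_hits <- function() {
  data.frame(read_id = character(0), target = character(0),
             offset = integer(0), strand = character(0),
             mismatches = integer(0), len = integer(0),
             stringsAsFactors = FALSE)
}

# Strict mismatch count: a position matches only when both letters are equal
# AND in {A,C,G,T}; anything else (N, ambiguity codes) mismatches everything,
# so all-N spacers can never be matched.
.strict_mm <- function(read_chars, win) {
  w <- strsplit(win, "", fixed = TRUE)[[1]]
  sum(!(read_chars == w & read_chars %in% c("A", "C", "G", "T")))
}

# Seeded all-hits search for a batch of oriented, N-free patterns of equal
# length: the pattern is split into max_mismatch + 1 contiguous seeds, so at
# the mismatch budget at least one seed must match exactly (pigeonhole).
# Seeds are located with exact multi-pattern matching (PDict) and candidate
# placements verified by direct comparison. Patterns are all-ACGT here, so
# letterwise comparison against the target (where any non-ACGT letter
# mismatches) is exactly what neditStartingAt(fixed = TRUE) counts.
.seeded_batch_hits <- function(pats, targets, max_mismatch) {
  out <- vector("list", length(pats))
  if (length(pats) == 0L) return(out)
  L <- nchar(pats[1])
  pset <- Biostrings::DNAStringSet(pats)
  b <- floor(seq(0, L, length.out = max_mismatch + 2L))
  pdicts <- lapply(seq_len(max_mismatch + 1L), function(j) {
    Biostrings::PDict(Biostrings::subseq(pset, b[j] + 1L, b[j + 1]))
  })
  twidths <- Biostrings::width(targets)
  for (t in seq_along(targets)) {
    max_start <- twidths[t] - L + 1L
    if (max_start < 1L) next
    subject <- targets[[t]]
    cand_pat <- integer(0)
    cand_start <- integer(0)
    for (j in seq_along(pdicts)) {
      m <- Biostrings::matchPDict(pdicts[[j]], subject)
      sl <- Biostrings::startIndex(m)
      ln <- lengths(sl)
      nz <- which(ln > 0L)
      if (length(nz) == 0L) next
      cand_pat <- c(cand_pat, rep.int(nz, ln[nz]))
      cand_start <- c(cand_start, unlist(sl[nz], use.names = FALSE) - b[j])
    }
    ok <- cand_start >= 1L & cand_start <= max_start
    cand_pat <- cand_pat[ok]; cand_start <- cand_start[ok]
    if (length(cand_pat) == 0L) next
    dup <- duplicated(cand_pat * (max_start + 1) + cand_start)
    cand_pat <- cand_pat[!dup]; cand_start <- cand_start[!dup]
    sp <- split(cand_start, cand_pat)
    for (pstr in names(sp)) {
      p <- as.integer(pstr)
      st <- sp[[pstr]]
      mm <- Biostrings::neditStartingAt(pset[[p]], subject, starting.at = st,
                                        with.indels = FALSE, fixed = TRUE)
      keep <- mm <= max_mismatch
      if (!any(keep)) next
      out[[p]] <- rbind(out[[p]], data.frame(
        target = names(targets)[t], offset = st[keep] - 1L,
        mismatches = as.integer(mm[keep]), stringsAsFactors = FALSE))
    }
  }
  out
}

# All ungapped hits of one pattern (already oriented) against the targets.
# General path used for patterns containing non-ACGT letters.
.pattern_hits <- function(pat_char, targets, target_chars, max_mismatch) {
  L <- nchar(pat_char)
  pat <- Biostrings::DNAString(pat_char)
  m <- Biostrings::vmatchPattern(pat, targets, max.mismatch = max_mismatch,
                                 fixed = TRUE)
  pat_has_amb <- grepl("[^ACGT]", pat_char)
  pat_chars <- NULL
  out <- vector("list", length(targets))
  for (i in seq_along(targets)) {
    st <- Biostrings::start(m[[i]])
    if (length(st) == 0L) next
    wlen <- Biostrings::width(targets)[i]
    st <- st[st >= 1L & st + L - 1L <= wlen]
    if (length(st) == 0L) next
    mm <- Biostrings::neditStartingAt(pat, targets[[i]], starting.at = st,
                                      with.indels = FALSE, fixed = TRUE)
    wins <- substring(target_chars[i], st, st + L - 1L)
    needs <- pat_has_amb | grepl("[^ACGT]", wins)
    if (any(needs)) {
      if (is.null(pat_chars)) pat_chars <- strsplit(pat_char, "", fixed = TRUE)[[1]]
      mm[needs] <- vapply(wins[needs], .strict_mm, integer(1) + 0,
                          read_chars = pat_chars)
      keep <- mm <= max_mismatch
      st <- st[keep]; mm <- mm[keep]
      if (length(st) == 0L) next
    }
    out[[i]] <- data.frame(target = names(targets)[i], offset = st - 1L,
                           mismatches = as.integer(mm),
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}

#' Find every ungapped alignment of each read at a mismatch budget
#'
#' Full-sensitivity all-hits alignment: every placement of every read (both
#' strands) on every target record with at most `max_mismatch` mismatches is
#' reported. Bases outside `{A,C,G,T}` in either the read or the target count
#' as mismatches, so the all-`N` spacers of a repeat assembly can never be
#' matched. Reads too short to align reliably (shorter than
#' `2 * (max_mismatch + 1)` bases) are reported as unalignable (no hits), not
#' an error.
#'
#' @param reads A `data.frame(read_id, sequence)` or named character vector.
#' @param targets A `RepeatAssembly`, `DNAStringSet`, named character vector,
#'   or genome FASTA path.
#' @param max_mismatch Maximum mismatches admitted per alignment (default 1).
#' @return A `data.frame` with columns `read_id`, `target`, `offset` (0-based
#'   position of the alignment on the target), `strand` (`+`/`-`),
#'   `mismatches` and `len` (read length). A `-` hit means the reverse
#'   complement of the read matches the target forward strand at `offset`.
#' @export
align_all_hits <- function(reads, targets, max_mismatch = 1L) {
  reads <- .as_reads(reads)
  targets <- .as_targets(targets)
  if (is.null(names(targets)) || any(names(targets) == "")) {
    stop("all target records must be named")
  }
  min_len <- 2L * (max_mismatch + 1L)
  useq <- unique(reads$sequence)
  useq <- useq[nchar(useq) >= min_len]
  # oriented patterns: forward and reverse complement of every read sequence
  clean <- !grepl("[^ACGT]", useq)
  rcs <- character(length(useq))
  if (any(clean)) {
    rcs[clean] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(useq[clean])))
  }
  per_seq <- vector("list", length(useq))
  names(per_seq) <- useq
  add_hits <- function(k, h, strand) {
    if (is.null(h) || nrow(h) == 0L) return()
    h$strand <- strand
    per_seq[[k]] <<- rbind(per_seq[[k]], h)
  }
  # seeded batch path for N-free patterns, grouped by read length
  for (L in unique(nchar(useq[clean]))) {
    idx <- which(clean & nchar(useq) == L)
    fwd <- .seeded_batch_hits(useq[idx], targets, max_mismatch)
    rev <- .seeded_batch_hits(rcs[idx], targets, max_mismatch)
    for (q in seq_along(idx)) {
      add_hits(idx[q], fwd[[q]], "+")
      add_hits(idx[q], rev[[q]], "-")
    }
  }
  # general path for reads containing ambiguity letters
  if (any(!clean)) {
    target_chars <- as.character(targets)
    for (k in which(!clean)) {
      sq <- useq[k]
      rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sq)))
      add_hits(k, .pattern_hits(sq, targets, target_chars, max_mismatch), "+")
      add_hits(k, .pattern_hits(rc, targets, target_chars, max_mismatch), "-")
    }
  }
  for (k in seq_along(per_seq)) {
    h <- per_seq[[k]]
    if (is.null(h)) next
    h <- h[!duplicated(h[, c("target", "offset", "strand")]), , drop = FALSE]
    h$len <- nchar(useq[k])
    per_seq[[k]] <- h
  }
  ids_per_seq <- split(reads$read_id, factor(reads$sequence, levels = useq))
  out <- lapply(seq_along(useq), function(k) {
    h <- per_seq[[k]]
    if (is.null(h)) return(NULL)
    ids <- ids_per_seq[[k]]
    n <- nrow(h)
    data.frame(read_id = rep(ids, each = n),
               target = rep(h$target, length(ids)),
               offset = rep(h$offset, length(ids)),
               strand = rep(h$strand, length(ids)),
               mismatches = rep(h$mismatches, length(ids)),
               len = rep(h$len, length(ids)), stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) return(.empty_hits())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("read_id", "target", "offset", "strand", "mismatches", "len")]
}

#' Assign reads to repeat types under the uniqueness conditions
#'
#' For each read, the best stratum is the minimum mismatch count over all its
#' hits; the read is assigned to a repeat type only when every best-stratum
#' hit targets that single type (multiple positions within the type are
#' allowed). Reads with best-stratum hits in two or more types are
#' cross-type ambiguous and excluded from per-type counts; reads with no hits
#' are unmapped.
#'
#' @param hits Hit table from [align_all_hits()] against a repeat assembly.
#' @param read_ids Character vector of all read ids in the dataset (so that
#'   unmapped reads appear in the output).
#' @return A `data.frame` with columns `read_id`, `status` (`assigned`,
#'   `cross_type_ambiguous` or `unmapped`), `type_name` (`NA` unless
#'   assigned), `best_mm` (best mismatch stratum, `NA` if unmapped) and
#'   `hit_types` (comma-separated best-stratum types, kept for ambiguous
#'   reads because merged tree nodes can recover them).
#' @export
assign_to_types <- function(hits, read_ids) {
  read_ids <- unique(as.character(read_ids))
  res <- data.frame(read_id = read_ids, status = "unmapped",
                    type_name = NA_character_, best_mm = NA_integer_,
                    hit_types = "", stringsAsFactors = FALSE)
  if (nrow(hits) > 0L) {
    sp <- split(seq_len(nrow(hits)), hits$read_id)
    ids <- names(sp)
    info <- lapply(sp, function(idx) {
      mm <- hits$mismatches[idx]
      m_star <- min(mm)
      tys <- sort(unique(hits$target[idx][mm == m_star]))
      list(m_star = m_star, tys = tys)
    })
    pos <- match(ids, res$read_id)
    known <- !is.na(pos)
    ids <- ids[known]; info <- info[known]; pos <- pos[known]
    res$best_mm[pos] <- vapply(info, function(x) x$m_star, integer(1) + 0)
    res$hit_types[pos] <- vapply(info, function(x) paste(x$tys, collapse = ","),
                                 character(1))
    n_types <- vapply(info, function(x) length(x$tys), integer(1))
    res$status[pos] <- ifelse(n_types == 1L, "assigned", "cross_type_ambiguous")
    one <- pos[n_types == 1L]
    res$type_name[one] <- vapply(info[n_types == 1L], function(x) x$tys,
                                 character(1))
  }
  res
}

#' Mask assigned reads that also map outside their type's annotated instances
#'
#' Implements the optional masking condition: an assigned read is masked when
#' it has a genome alignment of equal or better quality (mismatches no
#' greater than its best repeat-assembly stratum) whose interval is not fully
#' contained in any flanked annotated instance of its assigned type.
#'
#' @param assignments Output of [assign_to_types()].
#' @param genome_hits Hits of the same reads against the genome FASTA, from
#'   [align_all_hits()] with the same `max_mismatch`.
#' @param assembly The `RepeatAssembly` whose segment map defines the flanked
#'   instance intervals.
#' @return `assignments` with the status of masked reads set to `"masked"`.
#' @export
apply_genome_mask <- function(assignments, genome_hits, assembly) {
  seg <- assembly$segment_map
  seg <- seg[seg$source_kind == "instance", , drop = FALSE]
  assigned <- which(assignments$status == "assigned")
  if (length(assigned) == 0L || nrow(genome_hits) == 0L) return(assignments)
  gh <- split(seq_len(nrow(genome_hits)), genome_hits$read_id)
  for (i in assigned) {
    idx <- gh[[assignments$read_id[i]]]
    if (is.null(idx)) next
    best <- assignments$best_mm[i]
    idx <- idx[genome_hits$mismatches[idx] <= best]
    if (length(idx) == 0L) next
    ty_seg <- seg[seg$record == assignments$type_name[i], , drop = FALSE]
    o <- genome_hits$offset[idx]
    e <- o + genome_hits$len[idx]
    ch <- genome_hits$target[idx]
    inside <- vapply(seq_along(idx), function(j) {
      any(ty_seg$chrom == ch[j] & ty_seg$start <= o[j] & e[j] <= ty_seg$end)
    }, logical(1))
    if (any(!inside)) assignments$status[i] <- "masked"
  }
  assignments
}

#' Effective dataset size: reads mapping to genome or canonical repeats
#'
#' The effective size of a ChIP or input dataset is the number of reads that
#' align at least once (at the mismatch budget) to the genome assembly or to
#' the canonical repeat sequences. This is the `S` (signal) or `C` (control)
#' denominator of the enrichment estimates.
#'
#' @param reads Reads as for [align_all_hits()].
#' @param genome Genome sequences or FASTA path.
#' @param canonicals Canonical library from [read_canonical_fasta()] (or
#'   `NULL` to count genome mappers only).
#' @param max_mismatch Mismatch budget (default 1).
#' @return Integer count of mapping reads.
#' @export
effective_dataset_size <- function(reads, genome, canonicals = NULL,
                                   max_mismatch = 1L) {
  reads <- .as_reads(reads)
  gh <- align_all_hits(reads, genome, max_mismatch = max_mismatch)
  mapped <- unique(gh$read_id)
  rest <- reads[!reads$read_id %in% mapped, , drop = FALSE]
  if (!is.null(canonicals) && nrow(rest) > 0L) {
    can <- stats::setNames(canonicals$sequence, canonicals$name)
    ch <- align_all_hits(rest, can, max_mismatch = max_mismatch)
    mapped <- c(mapped, unique(ch$read_id))
  }
  length(mapped)
}

#' Import all-hits alignments from SAM/BAM
#'
#' Ingests alignments produced by an external aligner against this package's
#' assembly FASTA, with secondary/alternative hits emitted. Records with
#' indels or clipping, or with more mismatches than the budget, are dropped.
#'
#' @param path SAM or BAM path. SAM files are converted in a temporary
#'   directory.
#' @param max_mismatch Mismatch budget (default 1).
#' @return A hit `data.frame` in the [align_all_hits()] layout.
#' @export
read_sam_hits <- function(path, max_mismatch = 1L) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "qwidth"),
    tag = "NM")
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  mapped <- bitwAnd(b$flag, 4L) == 0L
  if (!any(mapped)) return(.empty_hits())
  nm <- b$tag$NM[mapped]
  if (is.null(b$tag$NM) || anyNA(nm)) {
    stop("SAM/BAM records lack the NM tag; re-align emitting NM ",
         "(e.g. bwa samse/aln with default tags)")
  }
  cigar <- b$cigar[mapped]
  ungapped <- !grepl("[IDNSHP]", cigar)
  keep <- ungapped & nm <= max_mismatch
  data.frame(
    read_id = b$qname[mapped][keep],
    target = as.character(b$rname[mapped][keep]),
    offset = b$pos[mapped][keep] - 1L,
    strand = ifelse(bitwAnd(b$flag[mapped][keep], 16L) > 0L, "-", "+"),
    mismatches = as.integer(nm[keep]),
    len = b$qwidth[mapped][keep],
    stringsAsFactors = FALSE)
}

#' Per-type read counts from assignments
#'
#' @param assignments Output of [assign_to_types()] (optionally after
#'   [apply_genome_mask()]).
#' @param types Optional character vector of the full type universe, so types
#'   with zero assigned reads appear with `n_assigned = 0`.
#' @return A `data.frame(type, n_assigned, n_ambiguous_involving_type)`.
#' @export
count_reads_by_type <- function(assignments, types = NULL) {
  assigned <- assignments[assignments$status == "assigned", , drop = FALSE]
  amb <- assignments[assignments$status == "cross_type_ambiguous", , drop = FALSE]
  amb_types <- unlist(strsplit(amb$hit_types, ",", fixed = TRUE))
  if (is.null(types)) {
    types <- sort(unique(c(assigned$type_name, amb_types)))
  }
  n_assigned <- as.integer(table(factor(assigned$type_name, levels = types)))
  n_amb <- as.integer(table(factor(amb_types, levels = types)))
  data.frame(type = types, n_assigned = n_assigned,
             n_ambiguous_involving_type = n_amb, stringsAsFactors = FALSE)
}

# Map assembly-record offsets to segment rows; hits overlapping a spacer by a
# mismatched base are attributed to the segment with the largest overlap.
.hit_segment <- function(seg, record, offset, len) {
  cand <- which(seg$record == record &
                  seg$offset_start < offset + len & offset < seg$offset_end)
  if (length(cand) == 0L) return(NA_integer_)
  if (length(cand) == 1L) return(cand)
  ov <- pmin(seg$offset_end[cand], offset + len) -
    pmax(seg$offset_start[cand], offset)
  cand[which.max(ov)]
}

#' Fractional per-instance read counts for instance-level analyses
#'
#' A read assigned to a type that hits several instance segments of that type
#' at its best stratum is attributed fractionally, `1/k` to each of the `k`
#' segments, so instance-level totals preserve the type-level count.
#' Type-level counts remain integer.
#'
#' @param hits Hit table from [align_all_hits()] against the assembly.
#' @param assembly The `RepeatAssembly`.
#' @param assignments Output of [assign_to_types()].
#' @return A `data.frame(instance_id, record, count)`.
#' @export
count_reads_by_instance <- function(hits, assembly, assignments) {
  seg <- assembly$segment_map
  assigned <- assignments[assignments$status == "assigned", , drop = FALSE]
  counts <- stats::setNames(numeric(nrow(seg)), seq_len(nrow(seg)))
  hsp <- split(seq_len(nrow(hits)), hits$read_id)
  for (i in seq_len(nrow(assigned))) {
    idx <- hsp[[assigned$read_id[i]]]
    idx <- idx[hits$mismatches[idx] == assigned$best_mm[i] &
                 hits$target[idx] == assigned$type_name[i]]
    segs <- unique(vapply(idx, function(j) {
      .hit_segment(seg, hits$target[j], hits$offset[j], hits$len[j])
    }, integer(1)))
    segs <- segs[!is.na(segs) & seg$source_kind[segs] == "instance"]
    if (length(segs) > 0L) counts[segs] <- counts[segs] + 1 / length(segs)
  }
  keep <- which(seg$source_kind == "instance")
  data.frame(instance_id = seg$instance_id[keep], record = seg$record[keep],
             count = unname(counts[keep]), stringsAsFactors = FALSE)
}
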