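#' Positional sequencing-error model
#'
#' Substitution probabilities per read position, interpolated linearly from
#' the first-position rate to the last (defaults follow the Illumina 1G
#' profile observed in 32-bp ChIP reads: 5.4e-3 at the first base rising to
#' 1.0e-2 at the last), plus a conditional substitution matrix giving, for
#' each true base, the distribution of the erroneous base (default uniform
#' over the three alternatives).
#'
#' @param first Error rate at read position 1.
#' @param last Error rate at the final position.
#' @param L Read length (default 32).
#' @param matrix Optional 4x4 substitution matrix with zero diagonal and
#'   rows (named A,C,G,T) summing to 1.
#' @return An `ErrorModel`: list with `per_position_rates` (length `L`) and
#'   `substitution_matrix`.
#' @export
make_error_model <- function(first = 5.4e-3, last = 1.0e-2, L = 32L,
                             matrix = NULL) {
  if (L < 2L) stop("read length must be at least 2")
  if (first < 0 || last > 1 || first > last) {
    stop("need 0 <= first <= last <= 1")
  }
  bases <- c("A", "C", "G", "T")
  if (is.null(matrix)) {
    matrix <- matrix(1 / 3, 4, 4, dimnames = list(bases, bases))
    diag(matrix) <- 0
  }
  stopifnot(all(dim(matrix) == c(4L, 4L)), all(diag(matrix) == 0),
            all(abs(rowSums(matrix) - 1) < 1e-9))
  structure(list(per_position_rates = seq(first, last, length.out = L),
                 substitution_matrix = matrix),
            class = "ErrorModel")
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Substitute bases of a character vector of equal-length sequences according
# to per-position rates and the substitution matrix. Non-ACGT bases are left
# untouched.
.apply_position_errors <- function(seqs, model) {
  if (length(seqs) == 0L) return(seqs)
  L <- nchar(seqs[1])
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rates <- matrix(model$per_position_rates, nrow = nrow(mat), ncol = L,
                  byrow = TRUE)
  hit <- matrix(stats::runif(length(mat)) < rates, nrow = nrow(mat)) &
    matrix(mat %in% c("A", "C", "G", "T"), nrow = nrow(mat))
  idx <- which(hit)
  if (length(idx) > 0L) {
    sm <- model$substitution_matrix
    mat[idx] <- vapply(mat[idx], function(b) {
      sample(colnames(sm), 1L, prob = sm[b, ])
    }, character(1))
  }
  apply(mat, 1, paste, collapse = "")
}

#' Sample reads from a repeat assembly under an error model
#'
#' Draws reads uniformly from all non-spacer positions (windows containing
#' no `N`) of the assembly records, on both strands, to the requested
#' coverage; each read then suffers per-position substitutions according to
#' the error model. The source record and offset of every read are retained
#' as truth labels for mis-assignment analysis.
#'
#' @param assembly A `RepeatAssembly`.
#' @param coverage Mean per-base coverage of the non-spacer sequence
#'   (default 100, the depth used for mis-alignment-rate estimation).
#' @param model An `ErrorModel` from [make_error_model()].
#' @param seed Random seed (required).
#' @param read_len Read length; defaults to the model's length.
#' @return A `data.frame(read_id, sequence, true_record, true_offset,
#'   true_strand)`.
#' @export
sample_assembly_reads <- function(assembly, coverage = 100, model, seed,
                                  read_len = length(model$per_position_rates)) {
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  recs <- as.character(assembly$records)
  # candidate start offsets (0-based) of N-free windows per record
  cand <- lapply(recs, function(r) {
    L <- nchar(r)
    if (L < read_len) return(integer(0))
    isn <- strsplit(r, "", fixed = TRUE)[[1]] %in% c("A", "C", "G", "T")
    ok <- which(stats::filter(as.integer(isn), rep(1, read_len),
                              sides = 1) == read_len) # ends of clean windows
    as.integer(ok - read_len) # 0-based starts
  })
  names(cand) <- names(recs)
  total_cand <- sum(lengths(cand))
  if (total_cand == 0L) stop("assembly has no N-free window of length ", read_len)
  non_spacer <- sum(vapply(strsplit(recs, "", fixed = TRUE), function(x) {
    sum(x != "N")
  }, numeric(1)))
  n_reads <- max(1L, round(coverage * non_spacer / read_len))
  rec_pick <- sample(rep(names(cand), lengths(cand)), n_reads, replace = TRUE)
  offs <- vapply(rec_pick, function(rn) {
    v <- cand[[rn]]
    v[sample.int(length(v), 1L)]
  }, integer(1))
  strands <- sample(c("+", "-"), n_reads, replace = TRUE)
  seqs <- substring(recs[rec_pick], offs + 1L, offs + read_len)
  rc <- strands == "-"
  if (any(rc)) {
    seqs[rc] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[rc])))
  }
  seqs <- .apply_position_errors(seqs, model)
  data.frame(read_id = sprintf("simread%06d", seq_len(n_reads)),
             sequence = seqs, true_record = unname(rec_pick),
             true_offset = unname(offs), true_strand = strands,
             stringsAsFactors = FALSE)
}

#' Plant SNPs into sequences at a fixed per-base rate
#'
#' Independent per-base substitution at the given rate (default 8.3e-5, an
#' average observed SNP rate over 5-Mbp windows of a mammalian chromosome),
#' with the replacement base drawn uniformly from the three alternatives.
#'
#' @param sequences Named character vector (or `DNAStringSet`) of sequences.
#' @param rate Per-base SNP probability in `[0, 1)`.
#' @param seed Random seed (required).
#' @return A list with `sequences` (mutated, same names) and `snps`
#'   (`data.frame(seq_name, pos, ref, alt)` with 0-based positions).
#' @export
apply_snps <- function(sequences, rate = 8.3e-5, seed) {
  if (missing(seed)) stop("a seed is required")
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  set.seed(seed)
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  bases <- c("A", "C", "G", "T")
  snps <- list()
  out <- sequences
  for (nm in names(sequences)) {
    chars <- strsplit(sequences[[nm]], "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(length(chars)) < rate & chars %in% bases)
    if (length(hit) > 0L) {
      alt <- vapply(chars[hit], function(b) sample(setdiff(bases, b), 1L),
                    character(1))
      snps[[nm]] <- data.frame(seq_name = nm, pos = hit - 1L,
                               ref = chars[hit], alt = unname(alt),
                               stringsAsFactors = FALSE)
      chars[hit] <- alt
      out[[nm]] <- paste(chars, collapse = "")
    }
  }
  snps <- if (length(snps) > 0L) do.call(rbind, c(snps, make.row.names = FALSE))
  else data.frame(seq_name = character(0), pos = integer(0),
                  ref = character(0), alt = character(0))
  list(sequences = out, snps = snps)
}

#' False-positive and false-negative assignment rates per repeat type
#'
#' Confusion-matrix summary of a simulation round: for each repeat type `T`,
#' the false-positive rate is the fraction of reads assigned to `T` whose
#' true source is a different record, and the false-negative rate is the
#' fraction of reads truly from `T` that were not assigned to `T`.
#' Denominators are reported alongside the rates.
#'
#' @param truth `data.frame(read_id, true_record)` (e.g. from
#'   [sample_assembly_reads()]).
#' @param assignments Output of [assign_to_types()] on the sampled reads.
#' @return A `data.frame(type, fp_rate, fp_den, fn_rate, fn_den)`.
#' @export
misassignment_rates <- function(truth, assignments) {
  if (nrow(truth) == 0L) stop("empty truth set")
  m <- merge(truth[, c("read_id", "true_record")],
             assignments[, c("read_id", "status", "type_name")],
             by = "read_id", all.x = TRUE)
  types <- sort(unique(m$true_record))
  res <- lapply(types, function(ty) {
    called <- m$status == "assigned" & !is.na(m$type_name) & m$type_name == ty
    fp_den <- sum(called)
    fp <- if (fp_den > 0) sum(called & m$true_record != ty) / fp_den else 0
    from_ty <- m$true_record == ty
    fn_den <- sum(from_ty)
    fn <- sum(from_ty & !called) / fn_den
    data.frame(type = ty, fp_rate = fp, fp_den = fp_den,
               fn_rate = fn, fn_den = fn_den, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Default specification for a synthetic repeat dataset
#'
#' @param families Data frame with one row per repeat family and columns
#'   `name`, `canonical_len`, `n_instances`, `divergence` (per-base
#'   substitution probability between the canonical and each instance),
#'   `frac_unannotated` (fraction of extra, truncated copies planted in the
#'   genome but omitted from the annotation) and `theta` (true ChIP fold
#'   enrichment).
#' @param genome_bg_len Background (non-repeat) genome length.
#' @param read_len Read length (default 32).
#' @param n_chip,n_input Number of ChIP and input reads.
#' @param error_model Optional `ErrorModel` applied to the reads.
#' @param seed Random seed (required).
#' @return A `SyntheticRepeatSpec` list.
#' @export
synth_spec <- function(families, genome_bg_len = 20000L, read_len = 32L,
                       n_chip = 4000L, n_input = 4000L, error_model = NULL,
                       seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(is.data.frame(families),
            all(c("name", "canonical_len", "n_instances", "divergence",
                  "frac_unannotated", "theta") %in% names(families)))
  if (any(families$divergence < 0 | families$divergence > 0.3)) {
    stop("divergence must be in [0, 0.3]")
  }
  if (any(families$theta <= 0)) stop("theta must be positive")
  structure(list(families = families, genome_bg_len = genome_bg_len,
                 read_len = read_len, n_chip = n_chip, n_input = n_input,
                 error_model = error_model, seed = seed),
            class = "SyntheticRepeatSpec")
}

.mutate_seq <- function(seq, rate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit) > 0L) {
    chars[hit] <- vapply(chars[hit], function(b) sample(setdiff(bases, b), 1L),
                         character(1))
  }
  paste(chars, collapse = "")
}

#' Generate a complete synthetic repeat dataset with known truth
#'
#' Builds a genome containing planted repeat families: random canonical
#' sequences, diverged full-length instances, and (optionally) truncated
#' copies left out of the annotation to exercise the masking procedure. ChIP
#' reads over-sample each family's instance footprint by its true enrichment
#' factor `theta`; input reads are uniform over the genome. All truth
#' (read sources, instance coordinates, per-type `theta`) is recorded.
#'
#' @param spec A `SyntheticRepeatSpec` from [synth_spec()].
#' @param out_dir Optional directory; when given, writes `genome.fa`,
#'   `canonical.fa`, `repeats.out` (RepeatMasker-style), `chip.fastq`,
#'   `input.fastq` and truth TSVs.
#' @return A list with `genome` (named character), `canonicals`,
#'   `instances` (annotated subset, 0-based half-open), `all_copies`
#'   (including un-annotated ones), `chip`, `input` (read data frames with
#'   `true_source` labels), `theta` (named vector) and `spec`.
#' @export
synth_dataset <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "SyntheticRepeatSpec"))
  set.seed(spec$seed)
  fam <- spec$families
  L <- spec$read_len

  canonicals <- data.frame(
    name = fam$name, family = fam$name, repeat_class = "Synthetic",
    sequence = vapply(fam$canonical_len, .random_dna, character(1)),
    stringsAsFactors = FALSE)

  # lay out copies along one chromosome with random background between them
  copies <- list()
  for (i in seq_len(nrow(fam))) {
    n_unann <- stats::rbinom(1, fam$n_instances[i],
                             min(fam$frac_unannotated[i], 0.99))
    n_total <- fam$n_instances[i] + n_unann
    for (j in seq_len(n_total)) {
      s <- .mutate_seq(canonicals$sequence[i], fam$divergence[i])
      annotated <- j <= fam$n_instances[i]
      if (!annotated) { # truncated partial copy below annotation thresholds
        keep <- max(L + 4L, floor(nchar(s) * stats::runif(1, 0.3, 0.6)))
        if (keep >= nchar(s)) keep <- nchar(s) - 1L
        start <- sample(nchar(s) - keep, 1L)
        s <- substring(s, start, start + keep - 1L)
      }
      copies[[length(copies) + 1L]] <- list(type = fam$name[i], seq = s,
                                            annotated = annotated)
    }
  }
  if (length(copies) > 1L) copies <- copies[sample(length(copies))]
  n_gaps <- length(copies) + 1L
  gap_len <- pmax(2L * L, stats::rmultinom(1, spec$genome_bg_len,
                                           rep(1 / n_gaps, n_gaps))[, 1])
  chrom_parts <- character(0)
  pos <- 0L
  copy_rows <- list()
  for (k in seq_along(copies)) {
    g <- .random_dna(gap_len[k])
    chrom_parts <- c(chrom_parts, g)
    pos <- pos + nchar(g)
    cp <- copies[[k]]
    copy_rows[[k]] <- data.frame(
      type_name = cp$type, chrom = "chrSim", start = pos,
      end = pos + nchar(cp$seq), strand = sample(c("+", "-"), 1L),
      annotated = cp$annotated, stringsAsFactors = FALSE)
    seq_out <- cp$seq
    if (copy_rows[[k]]$strand == "-") {
      seq_out <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cp$seq)))
    }
    chrom_parts <- c(chrom_parts, seq_out)
    pos <- pos + nchar(cp$seq)
  }
  chrom_parts <- c(chrom_parts, .random_dna(gap_len[n_gaps]))
  genome <- c(chrSim = paste(chrom_parts, collapse = ""))
  all_copies <- do.call(rbind, copy_rows)
  instances <- all_copies[all_copies$annotated, , drop = FALSE]
  instances$annotated <- NULL
  rownames(instances) <- NULL

  glen <- nchar(genome[["chrSim"]])
  # a read "originates from" a copy when its window overlaps the copy, so
  # the enriched start-interval of copy k is [start - (L-1), end - 1],
  # clipped to valid read starts; copies are separated by >= 2L of
  # background, so these intervals never overlap
  cs <- pmax(all_copies$start - (L - 1L), 0L)
  ce <- pmin(all_copies$end - 1L, glen - L)
  copy_w <- ce - cs + 1L
  w_theta <- stats::setNames(fam$theta, fam$name)[all_copies$type_name]
  total_starts <- glen - L + 1L
  # background start intervals: the complement, in genome order
  ord <- order(cs)
  gap_lo <- c(0L, ce[ord] + 1L)
  gap_hi <- c(cs[ord] - 1L, glen - L)
  gap_w <- pmax(gap_hi - gap_lo + 1L, 0L)

  draw_reads <- function(n, enriched, prefix) {
    if (enriched) {
      # background weight shrinks so total weight matches the input library:
      # the realized ChIP/input proportion ratio of each family is then
      # exactly its theta
      w_bg <- total_starts - sum(copy_w * w_theta)
      if (w_bg <= 0) {
        stop("infeasible spec: enriched repeat footprint exceeds the genome")
      }
      seg_w <- c(w_bg, copy_w * w_theta)
    } else {
      seg_w <- c(sum(gap_w), copy_w)
    }
    pick <- sample(length(seg_w), n, replace = TRUE, prob = seg_w)
    starts <- integer(n)
    src <- character(n)
    for (r in seq_len(n)) {
      if (pick[r] == 1L) { # background: uniform over the complement
        g <- sample(length(gap_w), 1L, prob = gap_w)
        starts[r] <- gap_lo[g] + sample.int(gap_w[g], 1L) - 1L
        src[r] <- "background"
      } else {
        k <- pick[r] - 1L
        starts[r] <- cs[k] + sample.int(copy_w[k], 1L) - 1L
        src[r] <- all_copies$type_name[k]
      }
    }
    seqs <- substring(genome[["chrSim"]], starts + 1L, starts + L)
    strands <- sample(c("+", "-"), n, replace = TRUE)
    rc <- strands == "-"
    if (any(rc)) {
      seqs[rc] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[rc])))
    }
    if (!is.null(spec$error_model)) {
      seqs <- .apply_position_errors(seqs, spec$error_model)
    }
    data.frame(read_id = sprintf("%s%06d", prefix, seq_len(n)),
               sequence = seqs, true_source = src, true_offset = starts,
               stringsAsFactors = FALSE)
  }
  chip <- draw_reads(spec$n_chip, TRUE, "chip")
  input <- draw_reads(spec$n_input, FALSE, "input")

  out <- list(genome = genome, canonicals = canonicals,
              instances = instances, all_copies = all_copies,
              chip = chip, input = input,
              theta = stats::setNames(fam$theta, fam$name), spec = spec)
  if (!is.null(out_dir)) .write_synth_dataset(out, out_dir)
  out
}

.write_fastq <- function(reads, path) {
  qual <- strrep("I", nchar(reads$sequence))
  writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n", qual),
             path)
}

.write_synth_dataset <- function(d, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(d$genome),
                              file.path(out_dir, "genome.fa"))
  can <- Biostrings::DNAStringSet(stats::setNames(
    d$canonicals$sequence,
    paste0(d$canonicals$name, "#", d$canonicals$repeat_class, "/",
           d$canonicals$family)))
  Biostrings::writeXStringSet(can, file.path(out_dir, "canonical.fa"))
  # RepeatMasker-style .out: three header lines then whitespace columns
  hdr <- c("   SW  perc perc perc  query     position in query    matching repeat",
           "score  div. del. ins.  sequence  begin  end  (left)   repeat  class/family  begin end (left) ID",
           "")
  inst <- d$instances
  lines <- sprintf("  250  5.0  0.0  0.0  %s  %d  %d  (0)  %s  %s  Synthetic/%s  1  %d  (0)  %d",
                   inst$chrom, inst$start + 1L, inst$end,
                   ifelse(inst$strand == "-", "C", "+"), inst$type_name,
                   inst$type_name, inst$end - inst$start,
                   seq_len(nrow(inst)))
  writeLines(c(hdr, lines), file.path(out_dir, "repeats.out"))
  .write_fastq(d$chip, file.path(out_dir, "chip.fastq"))
  .write_fastq(d$input, file.path(out_dir, "input.fastq"))
  utils::write.table(d$chip[, c("read_id", "true_source", "true_offset")],
                     file.path(out_dir, "chip_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(d$input[, c("read_id", "true_source", "true_offset")],
                     file.path(out_dir, "input_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(type = names(d$theta), theta = d$theta),
                     file.path(out_dir, "theta_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(jsonlite::toJSON(list(seed = d$spec$seed,
                                   read_len = d$spec$read_len,
                                   n_chip = d$spec$n_chip,
                                   n_input = d$spec$n_input),
                              auto_unbox = TRUE, pretty = TRUE),
             file.path(out_dir, "spec.json"))
  invisible(out_dir)
}
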