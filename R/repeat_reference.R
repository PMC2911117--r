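#' Read a canonical (consensus) repeat library from FASTA
#'
#' Parses a Repbase-style FASTA of canonical repeat sequences. Headers are
#' expected in the `name#class/family` convention used by Repbase and
#' RepeatMasker libraries (e.g. `IAPLTR1#LTR/ERVK`); the class and family
#' tokens are optional and default to `"Unknown"`. Sequences are uppercased.
#'
#' @param path Path to a FASTA file.
#' @return A `data.frame` with columns `name`, `family`, `repeat_class` and
#'   `sequence`, one row per FASTA entry.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">IAPLTR1#LTR/ERVK", "ACGTACGT", ">B1#SINE/Alu", "ggcc"), fa)
#' read_canonical_fasta(fa)
#' @export
read_canonical_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) {
    stop("empty canonical repeat FASTA: ", path)
  }
  headers <- names(seqs)
  name <- sub("[#[:space:]].*$", "", headers)
  if (any(name == "")) stop("FASTA entry with empty name in ", path)
  dup <- name[duplicated(name)]
  if (length(dup) > 0L) {
    stop("duplicate canonical repeat name(s): ", paste(unique(dup), collapse = ", "))
  }
  ann <- rep("", length(headers))
  has_ann <- grepl("#", headers, fixed = TRUE)
  ann[has_ann] <- sub("^[^#]*#", "", headers[has_ann])
  ann <- sub("[[:space:]].*$", "", ann)
  repeat_class <- ifelse(ann == "", "Unknown", sub("/.*$", "", ann))
  family <- ifelse(grepl("/", ann), sub("^[^/]*/", "", ann), "Unknown")
  sequence <- toupper(as.character(seqs))
  if (any(nchar(sequence) < 1L)) {
    stop("zero-length canonical sequence for: ",
         paste(name[nchar(sequence) < 1L], collapse = ", "))
  }
  data.frame(name = name, family = family, repeat_class = repeat_class,
             sequence = unname(sequence), stringsAsFactors = FALSE)
}

#' Read RepeatMasker `.out` repeat-instance annotations
#'
#' Parses the standard RepeatMasker `.out` layout (three header lines, then
#' whitespace-delimited columns). Genomic coordinates, 1-based inclusive in
#' the file, are converted to the package-wide 0-based half-open convention;
#' the RepeatMasker complement flag `C` becomes strand `-`. Any
#' `#class/family` suffix on the matching-repeat column is stripped into the
#' family metadata; otherwise the dedicated class/family column is used.
#'
#' @param path Path to a RepeatMasker `.out` file.
#' @return A `data.frame` with columns `type_name`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand` (`+`/`-`), `family`, `repeat_class`.
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  if (length(lines) > 3L) lines <- lines[-(1:3)] else lines <- character(0)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep) + 3L
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(data.frame(type_name = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), family = character(0),
                      repeat_class = character(0), stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  parse_row <- function(f, ln) {
    if (length(f) < 11L) stop("malformed RepeatMasker line ", ln, ": too few fields")
    begin <- suppressWarnings(as.integer(f[6]))
    end <- suppressWarnings(as.integer(f[7]))
    if (is.na(begin) || is.na(end)) {
      stop("malformed coordinates on RepeatMasker line ", ln, ": '",
           f[6], "' / '", f[7], "'")
    }
    name <- f[10]
    cf <- f[11]
    if (grepl("#", name, fixed = TRUE)) {
      cf <- sub("^[^#]*#", "", name)
      name <- sub("#.*$", "", name)
    }
    c(chrom = f[5], begin = begin, end = end,
      strand = if (identical(f[9], "C")) "-" else "+",
      name = name, classfam = cf)
  }
  rows <- mapply(parse_row, fields, lineno, SIMPLIFY = FALSE)
  rows <- do.call(rbind, rows)
  cf <- rows[, "classfam"]
  data.frame(
    type_name = rows[, "name"],
    chrom = rows[, "chrom"],
    start = as.integer(rows[, "begin"]) - 1L,
    end = as.integer(rows[, "end"]),
    strand = rows[, "strand"],
    family = ifelse(grepl("/", cf), sub("^[^/]*/", "", cf), "Unknown"),
    repeat_class = ifelse(cf == "" | is.na(cf), "Unknown", sub("/.*$", "", cf)),
    stringsAsFactors = FALSE
  )
}

# Accept a genome as a DNAStringSet, a named character vector, or a FASTA path.
.as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    g <- Biostrings::readDNAStringSet(genome)
    names(g) <- sub("[[:space:]].*$", "", names(g))
    return(g)
  }
  if (is.character(genome) && !is.null(names(genome))) {
    return(Biostrings::DNAStringSet(toupper(genome)))
  }
  stop("genome must be a DNAStringSet, a named character vector, or a FASTA path")
}

#' Extract repeat-instance sequences with genomic flanks
#'
#' Slices each annotated instance out of the genome, extending it by
#' `flank_bp` on both sides (clipped at chromosome boundaries). Minus-strand
#' instances are returned as plus-strand genomic slices; strand is handled at
#' alignment time by also aligning the reverse complement of each read.
#'
#' @param genome Genome sequences (`DNAStringSet`, named character vector, or
#'   FASTA path).
#' @param instances Instance table from [read_repeatmasker_out()].
#' @param flank_bp Flank width in bp added on each side (default 13, half of
#'   a typical 26-bp read; set to `floor(read_length / 2)` for other read
#'   lengths).
#' @return The `instances` data.frame with added columns `flank_start`,
#'   `flank_end` (the clipped flanked interval, 0-based half-open) and
#'   `sequence`.
#' @export
extract_instance_sequences <- function(genome, instances, flank_bp = 13L) {
  genome <- .as_genome(genome)
  if (nrow(instances) == 0L) {
    instances$flank_start <- integer(0)
    instances$flank_end <- integer(0)
    instances$sequence <- character(0)
    return(instances)
  }
  missing <- setdiff(unique(instances$chrom), names(genome))
  if (length(missing) > 0L) {
    stop("chromosome(s) not found in genome: ", paste(missing, collapse = ", "))
  }
  clen <- Biostrings::width(genome)[match(instances$chrom, names(genome))]
  bad <- instances$start < 0L | instances$end > clen | instances$start >= instances$end
  if (any(bad)) {
    stop("instance interval(s) outside chromosome bounds at row(s): ",
         paste(which(bad), collapse = ", "))
  }
  fs <- pmax(instances$start - flank_bp, 0L)
  fe <- pmin(instances$end + flank_bp, clen)
  seqs <- vapply(seq_len(nrow(instances)), function(i) {
    as.character(Biostrings::subseq(genome[[instances$chrom[i]]],
                                    start = fs[i] + 1L, end = fe[i]))
  }, character(1))
  instances$flank_start <- as.integer(fs)
  instances$flank_end <- as.integer(fe)
  instances$sequence <- seqs
  instances
}

#' Build a repeat assembly (alignment target) from canonicals and instances
#'
#' Constructs one concatenated record per repeat type, in one of three modes:
#' `"canonical"` (consensus sequences only), `"instance"` (flanked genomic
#' instances only), or `"combined"` (canonical followed by all instances).
#' Within a record, segments are separated by spacer blocks of `spacer_len`
#' `'N'` characters so that no read of length up to `spacer_len` can bridge
#' two segments at a small mismatch budget. A segment map records, for every
#' non-spacer interval of every record, the source it was sliced from.
#'
#' @param canonicals Canonical library from [read_canonical_fasta()].
#' @param instance_seqs Flanked instance table from
#'   [extract_instance_sequences()], or `NULL` for `mode = "canonical"`.
#' @param mode One of `"combined"`, `"canonical"`, `"instance"`.
#' @param spacer_len Number of `'N'` characters between segments (default 80).
#' @param flank_bp Flank width recorded for bookkeeping (default 13).
#' @return A `RepeatAssembly` object: a list with elements `records`
#'   (`DNAStringSet`, one entry per repeat type), `segment_map` (a
#'   `data.frame` with `record`, `offset_start`, `offset_end` [0-based
#'   half-open offsets into the record], `source_kind`, `instance_id`,
#'   `chrom`, `start`, `end` [flanked genomic interval], `strand`),
#'   `spacer_len`, `flank_bp` and `mode`.
#' @export
build_assembly <- function(canonicals, instance_seqs = NULL,
                           mode = c("combined", "canonical", "instance"),
                           spacer_len = 80L, flank_bp = 13L) {
  mode <- match.arg(mode)
  spacer <- strrep("N", spacer_len)
  if (is.null(instance_seqs)) {
    instance_seqs <- data.frame(type_name = character(0), chrom = character(0),
                                flank_start = integer(0), flank_end = integer(0),
                                strand = character(0), sequence = character(0),
                                stringsAsFactors = FALSE)
  }
  unknown <- setdiff(unique(instance_seqs$type_name), canonicals$name)
  if (length(unknown) > 0L) {
    warning("skipping instances of unknown repeat type(s): ",
            paste(unknown, collapse = ", "))
    instance_seqs <- instance_seqs[!instance_seqs$type_name %in% unknown, ,
                                   drop = FALSE]
  }
  if (mode == "instance" && nrow(instance_seqs) == 0L) {
    stop("mode 'instance' requires at least one annotated instance")
  }

  segs <- list()
  records <- character(0)
  for (i in seq_len(nrow(canonicals))) {
    ty <- canonicals$name[i]
    inst <- instance_seqs[instance_seqs$type_name == ty, , drop = FALSE]
    pieces <- character(0)
    pieces_meta <- list()
    if (mode %in% c("combined", "canonical")) {
      pieces <- canonicals$sequence[i]
      pieces_meta[[1]] <- data.frame(
        source_kind = "canonical", instance_id = NA_character_,
        chrom = NA_character_, start = 0L,
        end = nchar(canonicals$sequence[i]), strand = "+",
        stringsAsFactors = FALSE)
    }
    if (mode %in% c("combined", "instance") && nrow(inst) > 0L) {
      for (j in seq_len(nrow(inst))) {
        pieces <- c(pieces, inst$sequence[j])
        pieces_meta[[length(pieces_meta) + 1L]] <- data.frame(
          source_kind = "instance",
          instance_id = paste0(ty, ".i", j),
          chrom = inst$chrom[j], start = inst$flank_start[j],
          end = inst$flank_end[j], strand = inst$strand[j],
          stringsAsFactors = FALSE)
      }
    }
    if (length(pieces) == 0L) next
    rec <- paste(pieces, collapse = spacer)
    off <- 0L
    for (k in seq_along(pieces)) {
      m <- pieces_meta[[k]]
      m$record <- ty
      m$offset_start <- off
      m$offset_end <- off + nchar(pieces[k])
      segs[[length(segs) + 1L]] <- m
      off <- off + nchar(pieces[k]) + spacer_len
    }
    records[ty] <- rec
  }
  if (length(records) == 0L) stop("assembly has no records")
  segment_map <- do.call(rbind, segs)
  segment_map <- segment_map[, c("record", "offset_start", "offset_end",
                                 "source_kind", "instance_id", "chrom",
                                 "start", "end", "strand")]
  rownames(segment_map) <- NULL
  structure(list(records = Biostrings::DNAStringSet(records),
                 segment_map = segment_map,
                 spacer_len = as.integer(spacer_len),
                 flank_bp = as.integer(flank_bp),
                 mode = mode),
            class = "RepeatAssembly")
}

#' @export
print.RepeatAssembly <- function(x, ...) {
  cat("RepeatAssembly (mode=", x$mode, "): ", length(x$records),
      " record(s), ", nrow(x$segment_map), " segment(s), spacer=",
      x$spacer_len, "N, flank=", x$flank_bp, "bp\n", sep = "")
  invisible(x)
}

#' Write an assembly to FASTA, segment-map TSV and instance BED
#'
#' @param assembly A `RepeatAssembly`.
#' @param out_prefix Output path prefix; writes `<prefix>.fa`,
#'   `<prefix>.segments.tsv` and `<prefix>.instances.bed` (0-based half-open).
#' @return Invisibly, the paths written.
#' @export
export_assembly <- function(assembly, out_prefix) {
  fa <- paste0(out_prefix, ".fa")
  tsv <- paste0(out_prefix, ".segments.tsv")
  bed <- paste0(out_prefix, ".instances.bed")
  Biostrings::writeXStringSet(assembly$records, fa)
  meta <- assembly$segment_map
  meta$spacer_len <- assembly$spacer_len
  meta$flank_bp <- assembly$flank_bp
  meta$mode <- assembly$mode
  utils::write.table(meta, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  inst <- assembly$segment_map[assembly$segment_map$source_kind == "instance", ,
                               drop = FALSE]
  if (nrow(inst) > 0L) {
    bed_df <- data.frame(inst$chrom, inst$start, inst$end, inst$instance_id,
                         0L, inst$strand)
    utils::write.table(bed_df, bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    file.create(bed)
  }
  invisible(c(fasta = fa, segments = tsv, bed = bed))
}

#' Load an assembly previously written by [export_assembly()]
#'
#' @param fasta Assembly FASTA path.
#' @param segments_tsv Segment-map TSV path.
#' @return A `RepeatAssembly`.
#' @export
import_assembly <- function(fasta, segments_tsv) {
  records <- Biostrings::readDNAStringSet(fasta)
  names(records) <- sub("[[:space:]].*$", "", names(records))
  meta <- utils::read.table(segments_tsv, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  spacer_len <- if ("spacer_len" %in% names(meta)) meta$spacer_len[1] else 80L
  flank_bp <- if ("flank_bp" %in% names(meta)) meta$flank_bp[1] else 13L
  mode <- if ("mode" %in% names(meta)) meta$mode[1] else "combined"
  segment_map <- meta[, c("record", "offset_start", "offset_end",
                          "source_kind", "instance_id", "chrom",
                          "start", "end", "strand")]
  structure(list(records = records, segment_map = segment_map,
                 spacer_len = as.integer(spacer_len),
                 flank_bp = as.integer(flank_bp), mode = mode),
            class = "RepeatAssembly")
}
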