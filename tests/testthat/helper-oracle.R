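# Independent brute-force oracles and small fixture builders used across the
# suite. The oracle aligner slides each read (both orientations) over every
# offset of every target, counting strict mismatches; it shares no code with
# align_all_hits().

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  chars <- rev(strsplit(s, "", fixed = TRUE)[[1]])
  paste(ifelse(chars %in% names(comp), comp[chars], "N"), collapse = "")
}

oracle_mismatches <- function(read, window) {
  x <- strsplit(read, "", fixed = TRUE)[[1]]
  w <- strsplit(window, "", fixed = TRUE)[[1]]
  sum(!(x == w & x %in% c("A", "C", "G", "T")))
}

oracle_align <- function(reads, targets, max_mismatch = 1L) {
  if (is.character(targets)) tchars <- targets else
    tchars <- setNames(as.character(targets), names(targets))
  rows <- list()
  for (i in seq_len(nrow(reads))) {
    sq <- reads$sequence[i]
    L <- nchar(sq)
    if (L < 2L * (max_mismatch + 1L)) next
    for (tn in names(tchars)) {
      tl <- nchar(tchars[[tn]])
      if (tl < L) next
      for (off in 0:(tl - L)) {
        win <- substring(tchars[[tn]], off + 1L, off + L)
        for (strand in c("+", "-")) {
          pat <- if (strand == "+") sq else oracle_revcomp(sq)
          mm <- oracle_mismatches(pat, win)
          if (mm <= max_mismatch) {
            rows[[length(rows) + 1L]] <- data.frame(
              read_id = reads$read_id[i], target = tn, offset = off,
              strand = strand, mismatches = mm, len = L,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(read_id = character(0), target = character(0),
                      offset = integer(0), strand = character(0),
                      mismatches = integer(0), len = integer(0)))
  }
  do.call(rbind, rows)
}

hit_key <- function(h) {
  sort(paste(h$read_id, h$target, h$offset, h$strand, h$mismatches))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_dna <- function(s, rate) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < rate)
  bases <- c("A", "C", "G", "T")
  if (length(hit)) {
    chars[hit] <- vapply(chars[hit], function(b) sample(setdiff(bases, b), 1),
                         character(1))
  }
  paste(chars, collapse = "")
}

# Build a small canonical library + genome + RepeatMasker .out on disk.
# Two well-separated families; family A has two diverged instances, family B
# one. Returns paths and in-memory objects.
make_tiny_reference <- function(dir = tempfile("ref"), seed = 42) {
  set.seed(seed)
  dir.create(dir)
  canA <- random_dna(200)
  canB <- random_dna(180)
  instA1 <- mutate_dna(canA, 0.05)
  instA2 <- mutate_dna(canA, 0.08)
  instB1 <- mutate_dna(canB, 0.05)
  bg <- replicate(4, random_dna(400))
  chrom <- paste0(bg[1], instA1, bg[2], instA2, bg[3], instB1, bg[4])
  startA1 <- nchar(bg[1])
  startA2 <- nchar(bg[1]) + 200 + nchar(bg[2])
  startB1 <- startA2 + 200 + nchar(bg[3])
  fa <- file.path(dir, "lib.fa")
  writeLines(c(">repA#LTR/ERVK", canA, ">repB#SINE/Alu", canB), fa)
  gfa <- file.path(dir, "genome.fa")
  writeLines(c(">chr1", chrom), gfa)
  out <- file.path(dir, "rm.out")
  writeLines(c(
    "   SW  perc perc perc  query  position in query  matching repeat",
    "score  div. del. ins.  sequence begin end (left) repeat class/family begin end (left) ID",
    "",
    sprintf("  250 5.0 0.0 0.0 chr1 %d %d (0) + repA LTR/ERVK 1 200 (0) 1",
            startA1 + 1, startA1 + 200),
    sprintf("  230 8.0 0.0 0.0 chr1 %d %d (0) C repA LTR/ERVK 1 200 (0) 2",
            startA2 + 1, startA2 + 200),
    sprintf("  240 5.0 0.0 0.0 chr1 %d %d (0) + repB SINE/Alu 1 180 (0) 3",
            startB1 + 1, startB1 + 180)
  ), out)
  list(dir = dir, lib_fa = fa, genome_fa = gfa, rm_out = out,
       genome = c(chr1 = chrom),
       canonical = c(repA = canA, repB = canB),
       inst = data.frame(
         type_name = c("repA", "repA", "repB"), chrom = "chr1",
         start = c(startA1, startA2, startB1),
         end = c(startA1 + 200, startA2 + 200, startB1 + 180),
         strand = c("+", "-", "+"), stringsAsFactors = FALSE))
}

# Sample error-free reads of length L from a named character genome.
sample_genome_reads <- function(genome, n, L = 32L, prefix = "r") {
  chrom <- sample(names(genome), n, replace = TRUE)
  reads <- lapply(seq_len(n), function(i) {
    g <- genome[[chrom[i]]]
    st <- sample.int(nchar(g) - L + 1L, 1L)
    sq <- substring(g, st, st + L - 1L)
    if (runif(1) < 0.5) sq <- oracle_revcomp(sq)
    data.frame(read_id = paste0(prefix, i), sequence = sq,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, reads)
}

# Hit table realizing given per-signature read counts, e.g.
# sig_hits(list(c("A"), c("A","B")), c(10, 5)) gives 10 reads hitting only A
# and 5 hitting A and B at the same stratum.
sig_hits <- function(sets, counts, prefix = "sr") {
  ids <- sprintf("%s%05d", prefix, seq_len(sum(counts)))
  id_groups <- split(ids, rep(seq_along(sets), counts))
  read_col <- unlist(lapply(seq_along(sets), function(i) {
    rep(id_groups[[i]], each = length(sets[[i]]))
  }))
  target_col <- unlist(lapply(seq_along(sets), function(i) {
    rep(sets[[i]], times = counts[i])
  }))
  data.frame(read_id = read_col, target = target_col, offset = 0L,
             strand = "+", mismatches = 0L, len = 32L,
             stringsAsFactors = FALSE)
}
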