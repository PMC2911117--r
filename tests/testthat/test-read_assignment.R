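test_that("planted and reverse-complement reads are found at their source", {
  set.seed(1)
  targ <- c(recA = random_dna(500))
  read <- substring(targ[["recA"]], 101, 132)
  h <- align_all_hits(c(r1 = read), targ)
  expect_true(any(h$target == "recA" & h$offset == 100 & h$strand == "+" &
                    h$mismatches == 0))
  h2 <- align_all_hits(c(r2 = oracle_revcomp(read)), targ)
  expect_true(any(h2$offset == 100 & h2$strand == "-" & h2$mismatches == 0))
})

test_that("aligner equals the exhaustive sliding-window oracle", {
  # random reads, planted reads, and mutated planted reads over two targets
  set.seed(202)
  targets <- c(t1 = random_dna(2000), t2 = random_dna(1500))
  reads <- list()
  for (i in 1:15) { # planted, possibly with 1 substitution
    tn <- sample(names(targets), 1)
    st <- sample.int(nchar(targets[[tn]]) - 31L, 1L)
    sq <- substring(targets[[tn]], st, st + 31L)
    if (i %% 3 == 0) sq <- mutate_dna(sq, 0.04)
    if (i %% 2 == 0) sq <- oracle_revcomp(sq)
    reads[[i]] <- sq
  }
  for (i in 16:25) reads[[i]] <- random_dna(32) # random, mostly unmappable
  reads <- data.frame(read_id = paste0("r", seq_along(reads)),
                      sequence = unlist(reads), stringsAsFactors = FALSE)
  got <- align_all_hits(reads, targets, max_mismatch = 1L)
  want <- oracle_align(reads, targets, max_mismatch = 1L)
  expect_equal(hit_key(got), hit_key(want))
})

test_that("N bases mismatch everything, in reads and in targets", {
  set.seed(3)
  base <- random_dna(100)
  targets <- c(t = base)
  read <- substring(base, 11, 42)
  read_n <- paste0("N", substring(read, 2))
  h <- align_all_hits(c(a = read_n), targets)
  expect_equal(h$mismatches, 1L) # N in read costs one mismatch
  # an N in the target aligned against the read's N still counts as a
  # mismatch (it is not an exact-match position), so the hit carries 1
  targets_n <- c(t = paste0(substring(base, 1, 10), "N", substring(base, 12)))
  h2 <- align_all_hits(c(a = read_n), targets_n)
  expect_equal(h2$mismatches[h2$offset == 10], 1L)
  oracle <- oracle_align(data.frame(read_id = "a", sequence = read_n),
                         targets_n)
  expect_equal(hit_key(h2), hit_key(oracle))
})

test_that("hit lists are independent of read order", {
  set.seed(17)
  targets <- c(t1 = random_dna(800))
  reads <- sample_genome_reads(targets, 30)
  h1 <- align_all_hits(reads, targets)
  h2 <- align_all_hits(reads[rev(seq_len(nrow(reads))), ], targets)
  expect_equal(hit_key(h1), hit_key(h2))
})

test_that("assignment implements best-stratum uniqueness across types", {
  hits <- rbind(
    # within-type multi-hit: assigned
    data.frame(read_id = "r1", target = "A", offset = c(0L, 50L),
               strand = "+", mismatches = 0L, len = 32L),
    # equal-best hits in two types: ambiguous
    data.frame(read_id = "r2", target = c("C", "D"), offset = 0L,
               strand = "+", mismatches = 0L, len = 32L),
    # 0-mm hit in A beats 1-mm hit in B: assigned to A
    data.frame(read_id = "r3", target = c("A", "B"), offset = 0L,
               strand = "+", mismatches = c(0L, 1L), len = 32L))
  asg <- assign_to_types(hits, c("r1", "r2", "r3", "r4"))
  expect_equal(asg$status[asg$read_id == "r1"], "assigned")
  expect_equal(asg$type_name[asg$read_id == "r1"], "A")
  expect_equal(asg$status[asg$read_id == "r2"], "cross_type_ambiguous")
  expect_equal(asg$hit_types[asg$read_id == "r2"], "C,D")
  expect_equal(asg$type_name[asg$read_id == "r3"], "A")
  expect_equal(asg$status[asg$read_id == "r4"], "unmapped")
  # partition property
  expect_equal(sum(asg$status == "assigned"), 2L)
  expect_equal(sum(asg$status == "cross_type_ambiguous"), 1L)
  expect_equal(sum(asg$status == "unmapped"), 1L)
})

test_that("types sharing a segment lose the shared read but keep boundary reads", {
  # two repeat types carrying an identical 60-bp block; a read from the
  # shared block is excluded, reads from unique flanks are retained
  set.seed(29)
  shared <- random_dna(60)
  uniqC <- random_dna(120)
  uniqD <- random_dna(120)
  can <- data.frame(name = c("typeC", "typeD"), family = "F",
                    repeat_class = "X",
                    sequence = c(paste0(uniqC, shared), paste0(shared, uniqD)),
                    stringsAsFactors = FALSE)
  asm <- build_assembly(can, NULL, mode = "canonical")
  reads <- data.frame(
    read_id = c("shared", "fromC", "fromD"),
    sequence = c(substring(shared, 10, 41), substring(uniqC, 20, 51),
                 substring(uniqD, 20, 51)),
    stringsAsFactors = FALSE)
  hits <- align_all_hits(reads, asm)
  asg <- assign_to_types(hits, reads$read_id)
  expect_equal(asg$status[asg$read_id == "shared"], "cross_type_ambiguous")
  expect_equal(asg$type_name[asg$read_id == "fromC"], "typeC")
  expect_equal(asg$type_name[asg$read_id == "fromD"], "typeD")
})

test_that("assigned reads never have equal-or-better hits in another type", {
  ref <- make_tiny_reference(seed = 5)
  lib <- read_canonical_fasta(ref$lib_fa)
  inst <- read_repeatmasker_out(ref$rm_out)
  iseq <- extract_instance_sequences(ref$genome, inst, flank_bp = 13L)
  asm <- build_assembly(lib, iseq, mode = "combined")
  set.seed(6)
  reads <- sample_genome_reads(ref$genome, 120)
  hits <- align_all_hits(reads, asm)
  asg <- assign_to_types(hits, reads$read_id)
  oracle <- oracle_align(reads, asm$records, max_mismatch = 1L)
  for (i in which(asg$status == "assigned")) {
    oh <- oracle[oracle$read_id == asg$read_id[i], ]
    other <- oh[oh$target != asg$type_name[i], ]
    expect_true(all(other$mismatches > asg$best_mm[i]))
  }
  # partition property on a realistic mixture
  expect_equal(nrow(asg), 120L)
  expect_true(all(asg$status %in% c("assigned", "cross_type_ambiguous",
                                    "unmapped")))
})

test_that("masking removes reads mappable outside their type's instances", {
  # plant an un-annotated partial copy of repA in the genome background
  ref <- make_tiny_reference(seed = 55)
  lib <- read_canonical_fasta(ref$lib_fa)
  partial <- substring(lib$sequence[lib$name == "repA"], 40, 140)
  genome <- c(chr1 = paste0(ref$genome[["chr1"]], random_dna(50), partial,
                            random_dna(50)))
  iseq <- extract_instance_sequences(genome, ref$inst, flank_bp = 13L)
  asm <- build_assembly(lib, iseq, mode = "combined")
  # a read from inside the partial-copy region of the canonical
  rd <- data.frame(read_id = "p1",
                   sequence = substring(lib$sequence[1], 60, 91))
  # and one from a region of repA not present in the partial copy
  rd2 <- data.frame(read_id = "p2",
                    sequence = substring(lib$sequence[1], 160, 191))
  reads <- rbind(rd, rd2)
  hits <- align_all_hits(reads, asm)
  asg <- assign_to_types(hits, reads$read_id)
  expect_true(all(asg$status == "assigned"))
  gh <- align_all_hits(reads, genome)
  masked <- apply_genome_mask(asg, gh, asm)
  expect_equal(masked$status[masked$read_id == "p1"], "masked")
  expect_equal(masked$status[masked$read_id == "p2"], "assigned")
})

test_that("strictly worse outside hits do not trigger masking", {
  set.seed(77)
  can <- data.frame(name = "repQ", family = "F", repeat_class = "X",
                    sequence = random_dna(200), stringsAsFactors = FALSE)
  inst_seq <- can$sequence # identical instance
  outside <- mutate_dna(substring(can$sequence, 50, 120), 0.02)
  genome <- c(chr1 = paste0(random_dna(100), inst_seq, random_dna(100),
                            outside, random_dna(100)))
  inst <- data.frame(type_name = "repQ", chrom = "chr1", start = 100L,
                     end = 300L, strand = "+", stringsAsFactors = FALSE)
  iseq <- extract_instance_sequences(genome, inst, flank_bp = 13L)
  asm <- build_assembly(can, iseq, mode = "combined")
  reads <- data.frame(read_id = "q1", sequence = substring(can$sequence, 60, 91))
  hits <- align_all_hits(reads, asm)
  asg <- assign_to_types(hits, reads$read_id)
  gh <- align_all_hits(reads, genome)
  res <- apply_genome_mask(asg, gh, asm)
  # the outside copy diverged; whether the read is masked must agree with
  # whether its outside hit is within the best stratum
  out_hits <- gh[gh$offset >= 400 & gh$offset < 480, ]
  if (nrow(out_hits) == 0 || all(out_hits$mismatches > asg$best_mm[1])) {
    expect_equal(res$status[1], "assigned")
  } else {
    expect_equal(res$status[1], "masked")
  }
})

test_that("effective dataset size counts genome or canonical mappers", {
  ref <- make_tiny_reference(seed = 8)
  lib <- read_canonical_fasta(ref$lib_fa)
  set.seed(9)
  planted <- sample_genome_reads(ref$genome, 40, prefix = "g")
  random <- data.frame(read_id = paste0("x", 1:40),
                       sequence = replicate(40, random_dna(32)),
                       stringsAsFactors = FALSE)
  # all planted reads map; 32-bp random reads essentially never do
  expect_equal(effective_dataset_size(planted, ref$genome, lib), 40L)
  expect_lte(effective_dataset_size(random, ref$genome, lib), 1L)
  both <- rbind(planted, random)
  n <- effective_dataset_size(both, ref$genome, lib)
  expect_gte(n, 40L)
  expect_lte(n, 41L)
})

test_that("per-type and per-instance counts are consistent", {
  ref <- make_tiny_reference(seed = 12)
  lib <- read_canonical_fasta(ref$lib_fa)
  iseq <- extract_instance_sequences(ref$genome, ref$inst, flank_bp = 13L)
  asm <- build_assembly(lib, iseq, mode = "combined")
  set.seed(13)
  reads <- sample_genome_reads(ref$genome, 150)
  hits <- align_all_hits(reads, asm)
  asg <- assign_to_types(hits, reads$read_id)
  counts <- count_reads_by_type(asg, types = lib$name)
  expect_equal(sum(counts$n_assigned), sum(asg$status == "assigned"))
  expect_lte(sum(counts$n_assigned), nrow(reads))
  inst_counts <- count_reads_by_instance(hits, asm, asg)
  # fractional attribution preserves totals: instance counts cannot exceed
  # the type totals (reads hitting only the canonical segment are excluded)
  agg <- tapply(inst_counts$count, inst_counts$record, sum)
  for (ty in names(agg)) {
    expect_lte(agg[[ty]], counts$n_assigned[counts$type == ty] + 1e-9)
  }
})

test_that("SAM ingestion reproduces internal hits and filters indels", {
  ref <- make_tiny_reference(seed = 21)
  lib <- read_canonical_fasta(ref$lib_fa)
  iseq <- extract_instance_sequences(ref$genome, ref$inst, flank_bp = 13L)
  asm <- build_assembly(lib, iseq, mode = "combined")
  set.seed(22)
  reads <- sample_genome_reads(ref$genome, 60)
  hits <- align_all_hits(reads, asm)
  # write the exhaustive hit list as SAM (as an all-hits external aligner
  # would) and re-ingest it
  sam <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6",
           paste0("@SQ\tSN:", names(asm$records), "\tLN:",
                  Biostrings::width(asm$records)))
  seq_by_id <- setNames(reads$sequence, reads$read_id)
  body <- vapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    flag <- if (h$strand == "-") 16L else 0L
    sq <- seq_by_id[[h$read_id]]
    if (h$strand == "-") sq <- oracle_revcomp(sq)
    paste(h$read_id, flag, h$target, h$offset + 1L, 255,
          paste0(h$len, "M"), "*", 0, 0, sq, strrep("I", h$len),
          paste0("NM:i:", h$mismatches), sep = "\t")
  }, character(1))
  # one gapped record and one 2-mismatch record, both of which must drop
  extra <- c(paste("bad1", 0, names(asm$records)[1], 1, 255, "16M1D16M", "*",
                   0, 0, random_dna(32), strrep("I", 32), "NM:i:1", sep = "\t"),
             paste("bad2", 0, names(asm$records)[1], 1, 255, "32M", "*", 0, 0,
                   random_dna(32), strrep("I", 32), "NM:i:2", sep = "\t"))
  writeLines(c(hdr, body, extra), sam)
  got <- read_sam_hits(sam, max_mismatch = 1L)
  expect_false(any(got$read_id %in% c("bad1", "bad2")))
  # identical type counts through either route
  asg_int <- assign_to_types(hits, reads$read_id)
  asg_sam <- assign_to_types(got, reads$read_id)
  expect_equal(count_reads_by_type(asg_int, lib$name),
               count_reads_by_type(asg_sam, lib$name))
  expect_equal(hit_key(got), hit_key(hits))
})

test_that("SAM records without NM are rejected with advice", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:x\tLN:100",
               paste("r1", 0, "x", 1, 255, "32M", "*", 0, 0,
                     random_dna(32), strrep("I", 32), sep = "\t")), sam)
  expect_error(read_sam_hits(sam), "NM")
})
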