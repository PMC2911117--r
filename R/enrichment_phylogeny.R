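# Internal signature representation: each read is reduced to the set of
# targets hit at its best mismatch stratum; reads with identical sets are
# aggregated. Node read-set arithmetic then runs on signatures x counts.
.signatures_from_hits <- function(hits) {
  if (nrow(hits) == 0L) {
    return(list(sets = list(), counts = integer(0), reads = list()))
  }
  sp <- split(seq_len(nrow(hits)), hits$read_id)
  sig_of <- vapply(sp, function(idx) {
    mm <- hits$mismatches[idx]
    paste(sort(unique(hits$target[idx][mm == min(mm)])), collapse = "\r")
  }, character(1))
  by_sig <- split(names(sig_of), sig_of)
  list(sets = lapply(names(by_sig), function(s) strsplit(s, "\r", fixed = TRUE)[[1]]),
       counts = vapply(by_sig, length, integer(1), USE.NAMES = FALSE),
       reads = unname(by_sig))
}

#' Read set of a node (set of repeat sequences)
#'
#' A read is *aligned* to a node when at least one of its best-stratum hits
#' targets a member of the node, and *unique* to the node when every
#' best-stratum hit does. Unique reads are the ones usable for the node's
#' enrichment estimate.
#'
#' @param members Character vector of member sequence names (repeat types or
#'   instance segment ids).
#' @param hits Hit table from [align_all_hits()].
#' @return A list with `members`, `aligned_reads` and `unique_reads`
#'   (character vectors of read ids).
#' @export
node_read_set <- function(members, hits) {
  sigs <- .signatures_from_hits(hits)
  aligned <- vapply(sigs$sets, function(s) any(s %in% members), logical(1))
  uniq <- vapply(sigs$sets, function(s) all(s %in% members), logical(1))
  uniq <- uniq & vapply(sigs$sets, length, integer(1)) > 0L
  list(members = members,
       aligned_reads = sort(unlist(sigs$reads[aligned], use.names = FALSE)),
       unique_reads = sort(unlist(sigs$reads[uniq], use.names = FALSE)))
}

#' Reads uniquely assignable to a set of sequences
#'
#' @inheritParams node_read_set
#' @return Character vector of read ids all of whose best-stratum hits fall
#'   within `members`.
#' @export
node_unique_reads <- function(members, hits) {
  node_read_set(members, hits)$unique_reads
}

#' Read-set similarity between two nodes
#'
#' The similarity of two sequence sets is the ratio of reads shared by the
#' two sets to the total number of reads aligning to either set (Jaccard
#' index of the aligned read sets); the corresponding distance is one minus
#' the similarity. Two empty read sets have similarity 0 by convention.
#'
#' @param A,B Node read sets from [node_read_set()] (or any lists with an
#'   `aligned_reads` character vector).
#' @return Similarity in `[0, 1]`.
#' @export
readset_similarity <- function(A, B) {
  a <- A$aligned_reads; b <- B$aligned_reads
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

# Greedy agglomeration on precomputed signatures. `leaves` is a named list of
# member vectors; targets outside the leaf universe may still occur in
# signatures (such reads can never become unique, but they do align).
.build_tree_from_sigs <- function(sigs, leaves) {
  targets <- sort(unique(c(unlist(sigs$sets), unlist(leaves))))
  tid <- stats::setNames(seq_along(targets), targets)
  sig_ids <- lapply(sigs$sets, function(s) unname(tid[s]))
  cnt <- sigs$counts

  mem_mask <- function(members) {
    m <- logical(length(targets)); m[tid[members]] <- TRUE; m
  }
  n_unique <- function(mask) {
    if (length(cnt) == 0L) return(0L)
    sum(cnt[vapply(sig_ids, function(s) all(mask[s]), logical(1))])
  }
  aligned_vec <- function(mask) {
    vapply(sig_ids, function(s) any(mask[s]), logical(1))
  }

  leaves <- leaves[order(names(leaves))]
  n <- length(leaves)
  nodes <- data.frame(node_id = names(leaves), left = NA_character_,
                      right = NA_character_, is_leaf = TRUE,
                      n_aligned = NA_real_, n_unique = NA_real_,
                      gain = NA_real_, stringsAsFactors = FALSE)
  members <- leaves
  names(members) <- names(leaves)
  masks <- lapply(leaves, mem_mask)
  al <- lapply(masks, aligned_vec)
  nodes$n_aligned <- vapply(al, function(a) sum(cnt[a]), numeric(1))
  nodes$n_unique <- vapply(masks, n_unique, numeric(1))
  nodes$gain <- nodes$n_unique

  active <- names(leaves)
  step <- 0L
  while (length(active) > 1L) {
    step <- step + 1L
    best <- NULL
    for (i in seq_along(active)[-length(active)]) {
      for (j in (i + 1L):length(active)) {
        a <- al[[active[i]]]; b <- al[[active[j]]]
        u <- sum(cnt[a | b])
        sim <- if (u == 0) 0 else sum(cnt[a & b]) / u
        key <- sort(c(min(members[[active[i]]]), min(members[[active[j]]])))
        if (is.null(best) || sim > best$sim ||
            (sim == best$sim && (key[1] < best$key[1] ||
                                 (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = active[i], j = active[j], sim = sim, key = key)
        }
      }
    }
    nid <- paste0("node", step)
    mem <- sort(c(members[[best$i]], members[[best$j]]))
    members[[nid]] <- mem
    mk <- mem_mask(mem)
    masks[[nid]] <- mk
    al[[nid]] <- al[[best$i]] | al[[best$j]]
    nu <- n_unique(mk)
    gain <- nu - nodes$n_unique[nodes$node_id == best$i] -
      nodes$n_unique[nodes$node_id == best$j]
    nodes <- rbind(nodes, data.frame(
      node_id = nid, left = best$i, right = best$j, is_leaf = FALSE,
      n_aligned = sum(cnt[al[[nid]]]), n_unique = nu, gain = gain,
      stringsAsFactors = FALSE))
    active <- c(setdiff(active, c(best$i, best$j)), nid)
  }
  nodes$branch_display_length <- log10(1 + nodes$gain)
  structure(list(nodes = nodes, members = members, root = active,
                 sigs = sigs), class = "EnrichmentTree")
}

#' Build the enrichment phylogeny over repeat sets
#'
#' Greedy bottom-up grouping: starting from the leaves, the pair of nodes
#' with the highest read-set similarity is merged at every step, yielding a
#' binary tree after `n - 1` merges. Each node records the reads uniquely
#' assignable to its member set and the *gain* — unique reads that were not
#' unique in either child (for leaves, the gain is the unique count itself).
#' Every uniquely assignable read is gained exactly once, so gains sum to
#' the root's unique count. Similarity ties are broken lexicographically on
#' the smallest member names, making the topology independent of leaf input
#' order.
#'
#' @param leaves Character vector of leaf sequence names, or a named list of
#'   member vectors for pre-grouped leaves.
#' @param hits ChIP hit table from [align_all_hits()] (topology and unique
#'   counts use ChIP reads).
#' @return An `EnrichmentTree`: list with `nodes` (a `data.frame` of
#'   `node_id`, `left`, `right`, `is_leaf`, `n_aligned`, `n_unique`, `gain`,
#'   `branch_display_length = log10(1 + gain)`), `members`, `root`, `sigs`.
#' @export
build_tree <- function(leaves, hits) {
  if (!is.list(leaves)) {
    leaves <- stats::setNames(as.list(leaves), leaves)
  }
  if (length(leaves) < 2L) {
    warning("fewer than two leaves; returning a degenerate tree")
  }
  if (is.null(names(leaves)) || any(names(leaves) == "")) {
    stop("leaves must be named")
  }
  sigs <- .signatures_from_hits(hits)
  .build_tree_from_sigs(sigs, leaves)
}

#' @export
print.EnrichmentTree <- function(x, ...) {
  nl <- sum(x$nodes$is_leaf)
  cat("EnrichmentTree:", nl, "leaves,", nrow(x$nodes) - nl,
      "internal node(s); root unique reads:",
      x$nodes$n_unique[x$nodes$node_id == x$root], "\n")
  invisible(x)
}

#' Annotate a tree with per-node enrichment estimates
#'
#' For every node, the ChIP unique-read count `s` and the control unique
#' count `c` (computed over the identical member sets from the control hit
#' list) are fed to the Poisson fold-enrichment model; the node acquires an
#' MLE, CI bounds, a capped Z-score and a significance flag.
#'
#' @param tree An `EnrichmentTree` built from ChIP hits.
#' @param control_hits Control hit table from [align_all_hits()] against the
#'   same targets.
#' @param S,C Effective ChIP and control dataset sizes (positive).
#' @param alpha Significance level (default 0.05).
#' @param cap Z-score cap (default 10).
#' @return The tree with estimate columns added to `tree$nodes`.
#' @export
annotate_tree <- function(tree, control_hits, S, C, alpha = 0.05, cap = 10) {
  if (C <= 0 || S <= 0) stop("dataset sizes must be positive")
  csigs <- .signatures_from_hits(control_hits)
  cuniq <- vapply(tree$members[tree$nodes$node_id], function(mem) {
    if (length(csigs$counts) == 0L) return(0)
    sum(csigs$counts[vapply(csigs$sets, function(s) all(s %in% mem), logical(1))])
  }, numeric(1))
  est <- estimate_enrichment(tree$nodes$node_id, s = tree$nodes$n_unique,
                             c = cuniq, S = S, C = C, alpha = alpha, cap = cap)
  tree$nodes$c_unique <- cuniq
  tree$nodes$mle <- est$mle
  tree$nodes$ci_low <- est$ci_low
  tree$nodes$ci_high <- est$ci_high
  tree$nodes$zscore <- est$zscore
  tree$nodes$significant <- est$significant
  tree
}

#' Enrichment phylogeny over the instances of one repeat type
#'
#' Builds a tree whose leaves are the individual annotated instances of a
#' repeat type. Reads with any best-stratum hit outside the considered
#' instance set (for example in another repeat type) are discarded before
#' read sets are computed. Hits on the type's own canonical segment are
#' ignored for this purpose: the consensus is a proxy for the very instances
#' under study, not a distinct genomic locus a read could originate from.
#'
#' @param type_name The repeat type whose instances form the leaves.
#' @param assembly The `RepeatAssembly` (provides the instance segments).
#' @param hits ChIP hit table against the assembly.
#' @return An `EnrichmentTree` with instance segment ids as leaves.
#' @export
instance_tree <- function(type_name, assembly, hits) {
  seg <- assembly$segment_map
  inst <- seg[seg$record == type_name & seg$source_kind == "instance", ,
              drop = FALSE]
  if (nrow(inst) < 2L) {
    stop("instance tree requires at least two annotated instances of ",
         type_name)
  }
  sigs <- list(sets = list(), counts = integer(0), reads = list())
  if (nrow(hits) > 0L) {
    # drop hits on the type's canonical segment before taking best strata
    hit_seg <- vapply(seq_len(nrow(hits)), function(j) {
      if (hits$target[j] != type_name) return(NA_integer_)
      .hit_segment(seg, hits$target[j], hits$offset[j], hits$len[j])
    }, integer(1))
    canonical_hit <- !is.na(hit_seg) & seg$source_kind[hit_seg] == "canonical"
    hits <- hits[!canonical_hit, , drop = FALSE]
    hit_seg <- hit_seg[!canonical_hit]
    sp <- split(seq_len(nrow(hits)), hits$read_id)
    sig_str <- vapply(sp, function(idx) {
      mm <- hits$mismatches[idx]
      idx <- idx[mm == min(mm)]
      segs <- hit_seg[idx]
      if (anyNA(segs)) return(NA_character_) # best hit in another type
      ids <- seg$instance_id[segs]
      if (anyNA(ids) || !all(ids %in% inst$instance_id)) return(NA_character_)
      paste(sort(unique(ids)), collapse = "\r")
    }, character(1))
    keep <- !is.na(sig_str)
    by_sig <- split(names(sig_str)[keep], sig_str[keep])
    sigs <- list(
      sets = lapply(names(by_sig), function(s) strsplit(s, "\r", fixed = TRUE)[[1]]),
      counts = vapply(by_sig, length, integer(1), USE.NAMES = FALSE),
      reads = unname(by_sig))
  }
  leaves <- stats::setNames(as.list(inst$instance_id), inst$instance_id)
  .build_tree_from_sigs(sigs, leaves)
}

# Newick serialization; branch length is the log-scaled gain so that long
# branches mark nodes where many reads become uniquely assignable.
.newick_node <- function(tree, node_id) {
  row <- tree$nodes[tree$nodes$node_id == node_id, ]
  bl <- sprintf("%.10g", row$branch_display_length)
  if (row$is_leaf) return(paste0(node_id, ":", bl))
  paste0("(", .newick_node(tree, row$left), ",",
         .newick_node(tree, row$right), ")", node_id, ":", bl)
}

#' Write an enrichment tree as Newick plus a node-annotation table
#'
#' Branch lengths are `log10(1 + gain)`; every node (leaves included) is
#' labelled with its node id, and a companion TSV keyed by node id carries
#' the gain, unique counts and, when the tree has been annotated, the
#' enrichment estimate columns.
#'
#' @param tree An `EnrichmentTree` (annotated or not).
#' @param path Newick output path.
#' @param annotations_path Companion TSV path (default `<path>.tsv`).
#' @return Invisibly, the Newick string.
#' @export
write_newick <- function(tree, path, annotations_path = paste0(path, ".tsv")) {
  nwk <- paste0(.newick_node(tree, tree$root), ";")
  writeLines(nwk, path)
  ann <- tree$nodes
  ann$members <- vapply(tree$members[ann$node_id], paste, character(1),
                        collapse = ",")
  utils::write.table(ann, annotations_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(nwk)
}
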