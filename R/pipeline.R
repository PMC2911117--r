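#' Read a flat key=value run configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Keys with multiple comma-separated values become character vectors.
#'
#' @param path Config file path.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[`, character(1), 2))
  vals <- trimws(vapply(kv, `[`, character(1), 3))
  out <- lapply(vals, function(v) {
    parts <- trimws(strsplit(v, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) num else parts
  })
  stats::setNames(out, keys)
}

.pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the repeat-enrichment pipeline end to end
#'
#' Orchestrates reference building, per-mark read alignment and type
#' assignment (with optional masking), enrichment estimation against a
#' control library (or input-free relative normalization when no control is
#' given), clustering of the resulting enrichment matrix, and the
#' enrichment phylogeny. Writes per-stage tables and a manifest JSON with
#' parameters, seed and output checksums.
#'
#' @param config Named list (or path to a key=value file readable by
#'   [read_run_config()]) with entries: `genome` (FASTA), `repbase`
#'   (canonical FASTA), `rmout` (RepeatMasker `.out`), `marks` (named list
#'   or vector of FASTQ paths, one per mark), `control` (FASTQ path,
#'   optional), and optional parameters `max_mismatch` (1), `flank_bp`
#'   (13), `spacer_len` (80), `alpha` (0.05), `n_omit` (5), `n_resample`
#'   (100), `mask` (FALSE), `mode` ("combined"), `seed` (1).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  p <- function(key, default) {
    if (!is.null(config[[key]])) config[[key]] else default
  }
  max_mismatch <- as.integer(p("max_mismatch", 1L))
  flank_bp <- as.integer(p("flank_bp", 13L))
  spacer_len <- as.integer(p("spacer_len", 80L))
  alpha <- as.numeric(p("alpha", 0.05))
  mask <- isTRUE(as.logical(p("mask", FALSE)))
  mode <- as.character(p("mode", "combined"))
  seed <- as.integer(p("seed", 1L))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ref <- .pipeline_stage("build-reference", {
    canonicals <- read_canonical_fasta(config$genome_canonical %||% config$repbase)
    instances <- read_repeatmasker_out(config$rmout)
    inst_seqs <- extract_instance_sequences(config$genome, instances, flank_bp)
    assembly <- build_assembly(canonicals, inst_seqs, mode = mode,
                               spacer_len = spacer_len, flank_bp = flank_bp)
    export_assembly(assembly, file.path(out_dir, "reference"))
    list(canonicals = canonicals, assembly = assembly)
  })

  marks <- config$marks
  if (is.null(names(marks)) || any(names(marks) == "")) {
    names(marks) <- paste0("mark", seq_along(marks))
  }
  assign_one <- function(fq, label) {
    reads <- read_fastq(fq)
    hits <- align_all_hits(reads, ref$assembly, max_mismatch = max_mismatch)
    asg <- assign_to_types(hits, reads$read_id)
    if (mask) {
      gh <- align_all_hits(reads, config$genome, max_mismatch = max_mismatch)
      asg <- apply_genome_mask(asg, gh, ref$assembly)
    }
    counts <- count_reads_by_type(asg, types = ref$canonicals$name)
    utils::write.table(counts, file.path(out_dir, paste0(label, "_counts.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    size <- effective_dataset_size(reads, config$genome, ref$canonicals,
                                   max_mismatch = max_mismatch)
    list(hits = hits, assignments = asg, counts = counts, size = size)
  }
  mark_res <- .pipeline_stage("assign", {
    lapply(stats::setNames(names(marks), names(marks)), function(m) {
      assign_one(marks[[m]], m)
    })
  })

  have_control <- !is.null(config$control)
  if (have_control) {
    ctl <- .pipeline_stage("assign-control", assign_one(config$control, "control"))
    est_list <- .pipeline_stage("enrich", {
      lapply(names(mark_res), function(m) {
        cnt <- mark_res[[m]]$counts
        est <- estimate_enrichment(cnt$type, cnt$n_assigned,
                                   ctl$counts$n_assigned,
                                   S = mark_res[[m]]$size, C = ctl$size,
                                   alpha = alpha)
        utils::write.table(est, file.path(out_dir, paste0(m, "_enrichment.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        est
      })
    })
    names(est_list) <- names(mark_res)
    mle <- vapply(est_list, function(e) e$mle, numeric(nrow(est_list[[1]])))
    sig <- vapply(est_list, function(e) e$significant,
                  logical(nrow(est_list[[1]])))
    if (is.null(dim(mle))) {
      mle <- matrix(mle, nrow = 1); sig <- matrix(sig, nrow = 1)
      colnames(mle) <- colnames(sig) <- names(est_list)
    }
    rownames(mle) <- rownames(sig) <- est_list[[1]]$set_id
    if (nrow(mle) >= 2L && ncol(mle) >= 1L) {
      cl <- .pipeline_stage("cluster", cluster_types(mle, sig))
      export_heatmap_data(mle, sig, cl$order,
                          file.path(out_dir, "heatmap.tsv"))
    }
    tree_mark <- names(mark_res)[1]
    tr <- .pipeline_stage("tree", {
      tr <- build_tree(ref$canonicals$name, mark_res[[tree_mark]]$hits)
      tr <- annotate_tree(tr, ctl$hits, S = mark_res[[tree_mark]]$size,
                          C = ctl$size, alpha = alpha)
      write_newick(tr, file.path(out_dir, paste0(tree_mark, "_tree.nwk")))
      tr
    })
  } else {
    .pipeline_stage("normalize-relative", {
      counts <- vapply(mark_res, function(m) m$counts$n_assigned,
                       integer(nrow(mark_res[[1]]$counts)))
      rownames(counts) <- mark_res[[1]]$counts$type
      sizes <- vapply(mark_res, function(m) m$size, numeric(1))
      tab <- build_proportions(counts, sizes)
      rz <- relative_zscores(tab, n_omit = as.integer(p("n_omit", 5L)),
                             n_resample = as.integer(p("n_resample", 100L)),
                             seed = seed)
      utils::write.table(as.data.frame(rz$z),
                         file.path(out_dir, "relative_zscores.tsv"),
                         sep = "\t", quote = FALSE)
      utils::write.table(rz$background,
                         file.path(out_dir, "relative_background.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    })
  }

  outputs <- list.files(out_dir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    package = "repeatenrich",
    version = as.character(utils::packageVersion("repeatenrich")),
    parameters = list(max_mismatch = max_mismatch, flank_bp = flank_bp,
                      spacer_len = spacer_len, alpha = alpha, mask = mask,
                      mode = mode, seed = seed),
    inputs = lapply(config[intersect(names(config),
                                     c("genome", "repbase", "rmout", "control"))],
                    function(f) unname(tools::md5sum(f))),
    outputs = as.list(tools::md5sum(outputs)))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a three-state heatmap coding of an enrichment matrix
#'
#' Encodes the display rule for enrichment heatmaps: significantly enriched
#' cells on a red scale (positive log2 MLE), significantly depleted cells on
#' a blue scale (negative log2 MLE), and non-significant cells white (0). A
#' TSV is always produced; an image is drawn only when `image` is given.
#'
#' @param mle_matrix Numeric MLE matrix (types x marks).
#' @param significant Logical matrix of the same shape.
#' @param ordering Row ordering from [cluster_types()] (default natural).
#' @param path Output TSV path.
#' @param image Optional PNG path; requires the `pheatmap` package.
#' @return Invisibly, the encoded matrix (log2 MLE, 0 where non-significant).
#' @export
export_heatmap_data <- function(mle_matrix, significant,
                                ordering = seq_len(nrow(mle_matrix)),
                                path, image = NULL) {
  enc <- ifelse(significant, log2(mle_matrix), 0)
  state <- matrix("white", nrow(enc), ncol(enc), dimnames = dimnames(enc))
  state[significant & mle_matrix > 1] <- "red"
  state[significant & mle_matrix < 1] <- "blue"
  enc <- enc[ordering, , drop = FALSE]
  state <- state[ordering, , drop = FALSE]
  df <- data.frame(type = rownames(enc), enc,
                   state = apply(state, 1, paste, collapse = ","),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(image) && requireNamespace("pheatmap", quietly = TRUE)) {
    grDevices::png(image, width = 800, height = 1200)
    pheatmap::pheatmap(enc, cluster_rows = FALSE, cluster_cols = FALSE)
    grDevices::dev.off()
  }
  invisible(enc)
}
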