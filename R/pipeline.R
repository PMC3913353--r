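# End-to-end orchestration: flat key-value run configuration and the full
# design pipeline (curate -> align -> consensus -> enumerate -> partition ->
# screen -> merge), with every intermediate written to disk.

#' Run configuration
#'
#' A flat set of keys covering design parameters, curation criteria,
#' alignment and execution settings, and input/output paths.  Serializes
#' losslessly to a `key = value` text file.
#'
#' @param ... Overrides of the defaults (unknown keys are rejected).
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
    defaults <- list(
        fasta = NA_character_, taxonomy = NA_character_,
        reference = NA_character_, rank = "taxon",
        out_dir = NA_character_,
        probe_length = 25L, max_degeneracy = 2000,
        specificity_threshold = 0.88, max_cross_hyb = 100L,
        job_count = 1L,
        min_length = 1200L, max_length_prokaryote = 1600L,
        max_length_fungi = 1800L, max_unknown_fraction = 0.01,
        max_unknown_run = 5L, require_taxon = TRUE,
        large_group_threshold = 100L, homogeneity_margin = 0.10,
        max_retries = 2L, cores = 1L, seed = 1L)
    over <- list(...)
    if (length(over) > 0L && (is.null(names(over)) || any(!nzchar(names(over)))))
        stop("configuration overrides must be named", call. = FALSE)
    unknown <- setdiff(names(over), names(defaults))
    if (length(unknown) > 0L)
        stop("unknown configuration key(s): ",
             paste(unknown, collapse = ", "), call. = FALSE)
    cfg <- defaults
    for (k in names(over)) {
        v <- over[[k]]
        cfg[[k]] <- if (is.integer(defaults[[k]])) as.integer(v)
        else if (is.numeric(defaults[[k]])) as.numeric(v)
        else if (is.logical(defaults[[k]])) as.logical(v)
        else as.character(v)
    }
    structure(cfg, class = "run_config")
}

#' Read / write a run configuration file
#'
#' The file format is one `key = value` pair per line; `#` starts a
#' comment.  Unknown keys are rejected on read.
#'
#' @param path Configuration file path.
#' @return `read_run_config`: a `run_config`.
#' @export
read_run_config <- function(path) {
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", lines))
    bad <- lines[vapply(kv, length, integer(1)) != 3L]
    if (length(bad) > 0L)
        stop("malformed configuration line(s): ",
             paste(sQuote(bad), collapse = ", "), call. = FALSE)
    vals <- lapply(kv, `[[`, 3L)
    names(vals) <- vapply(kv, `[[`, character(1), 2L)
    do.call(run_config, vals)
}

#' @param config A `run_config`.
#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
    stopifnot(inherits(config, "run_config"))
    writeLines(vapply(names(config), function(k)
        sprintf("%s = %s", k, as.character(config[[k]])), character(1)),
        path)
    invisible(path)
}

.cfg_params <- function(config) {
    design_parameters(probe_length = config$probe_length,
                      max_degeneracy = config$max_degeneracy,
                      specificity_threshold = config$specificity_threshold,
                      max_cross_hyb = config$max_cross_hyb,
                      job_count = config$job_count)
}

.cfg_criteria <- function(config) {
    curation_criteria(min_length = config$min_length,
                      max_length_prokaryote = config$max_length_prokaryote,
                      max_length_fungi = config$max_length_fungi,
                      max_unknown_fraction = config$max_unknown_fraction,
                      max_unknown_run = config$max_unknown_run,
                      require_taxon = config$require_taxon)
}

.stage <- function(name, what, expr) {
    tryCatch(expr, error = function(e)
        stop(sprintf("stage '%s' failed (%s): %s", name, what,
                     conditionMessage(e)), call. = FALSE))
}

#' Run the full probe design pipeline
#'
#' Executes, in order: sequence + taxonomy input, database curation,
#' per-group alignment, consensus construction, probe enumeration,
#' worst-fit partitioning into `job_count` jobs, cross-hybridization
#' screening of every job (locally, with retry), and a deterministic
#' merge.  Every intermediate is written under `out_dir`; stage counts
#' are logged via `message()`.
#'
#' @param config A [run_config()] with at least `fasta`, `taxonomy`,
#'   `reference` and `out_dir` set.
#' @return Invisibly, a list with the curation result, consensus list,
#'   probe table, partition, merged screening results and all output
#'   paths.
#' @export
design_pipeline <- function(config) {
    stopifnot(inherits(config, "run_config"))
    for (k in c("fasta", "taxonomy", "reference", "out_dir"))
        if (is.na(config[[k]]))
            stop("configuration key '", k, "' is required", call. = FALSE)
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    set.seed(config$seed)
    params <- .cfg_params(config)

    records <- .stage("input", config$fasta,
        read_fasta(config$fasta, taxonomy = config$taxonomy,
                   rank = config$rank))
    reference <- .stage("input", config$reference,
        read_fasta(config$reference))
    message(sprintf("input: %d record(s)", nrow(records)))

    cur <- .stage("curate", "all groups",
        build_database(records, reference[1L, , drop = FALSE],
                       criteria = .cfg_criteria(config),
                       margin = config$homogeneity_margin))
    gdir <- file.path(config$out_dir, "groups")
    dir.create(gdir, showWarnings = FALSE)
    for (g in cur$groups)
        write_fasta(g$members, file.path(gdir, paste0(g$taxon, ".fasta")))
    report_path <- file.path(config$out_dir, "curation_report.tsv")
    write.table(cur$report, report_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    message(sprintf("curate: %d group(s), %d of %d record(s) kept",
                    length(cur$groups),
                    sum(cur$report$disposition == "kept"), nrow(records)))

    adir <- file.path(config$out_dir, "alignments")
    cdir <- file.path(config$out_dir, "consensus")
    dir.create(adir, showWarnings = FALSE)
    dir.create(cdir, showWarnings = FALSE)
    consensus <- list()
    probes <- list()
    for (g in cur$groups) {
        aln <- .stage("align", g$taxon,
            align_group(g, config$large_group_threshold))
        write_alignment(aln, file.path(adir, paste0(g$taxon, ".aln.fasta")))
        cons <- .stage("consensus", g$taxon,
            build_consensus(aln, taxon = g$taxon)$consensus)
        write_fasta(structure(cons$text, names = g$taxon),
                    file.path(cdir, paste0(g$taxon, ".fasta")))
        probes[[g$taxon]] <- .stage("enumerate", g$taxon,
            enumerate_probes(cons, params))
        consensus[[g$taxon]] <- cons
    }
    if (length(probes) == 0L)
        stop("stage 'design' failed: no groups survived curation",
             call. = FALSE)
    probes <- do.call(rbind, c(probes, list(make.row.names = FALSE)))
    probe_path <- file.path(config$out_dir, "probes.tsv")
    write_probes(probes, probe_path)
    message(sprintf("design: %d candidate probe(s), total degeneracy %.0f",
                    nrow(probes), sum(probes$weight)))

    part <- .stage("partition", "probes",
        worst_fit_partition(probes, config$job_count))
    write_job_files(part, file.path(config$out_dir, "jobs"))
    st <- load_stats(part$loads)
    message(sprintf("partition: %d job(s), mean load %.2f, load sd %.4g",
                    part$n_jobs, st$mean, st$sample_std))

    index <- build_screen_index(cur$groups, params$probe_length,
                                params$specificity_threshold)
    worker <- function(job) screen_probes(job, cur$groups, params, index)
    run <- .stage("screen", "jobs",
        run_jobs_local(part, worker, max_retries = config$max_retries,
                       cores = config$cores))
    results_path <- file.path(config$out_dir, "results.tsv")
    hits_path <- file.path(config$out_dir, "hits.tsv")
    write.table(run$results$results, results_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(run$results$hits, hits_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    manifest_path <- file.path(config$out_dir, "jobs_manifest.tsv")
    write.table(run$manifest, manifest_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    message(sprintf(
        "screen: %d expansion row(s), %d cross-hybridization(s), %d/%d probe(s) accepted",
        nrow(run$results$results), nrow(run$results$hits),
        length(unique(paste(run$results$results$taxon,
                            run$results$results$start)[
                      run$results$results$status == "accepted"])),
        nrow(probes)))

    invisible(list(curation = cur, consensus = consensus, probes = probes,
                   partition = part, results = run$results,
                   manifest = run$manifest,
                   paths = list(report = report_path, probes = probe_path,
                                results = results_path, hits = hits_path,
                                manifest = manifest_path,
                                groups = gdir, alignments = adir,
                                consensus = cdir)))
}
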