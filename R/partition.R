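# Degeneracy-weighted worst-fit partitioning of probes into N jobs, job
# load statistics, and a local executor with retry and deterministic merge
# (the local stand-in for a batch/grid back end).

#' Partition probes into N jobs by worst-fit on degeneracy weight
#'
#' Probes are sorted in descending weight order (ties keep input order)
#' and each is placed in the job with the largest remaining capacity
#' relative to the mean load -- equivalently, the currently lightest job,
#' ties going to the lowest job index.  The resulting jobs have almost
#' equal total weight: max load - min load never exceeds the largest
#' single weight.
#'
#' @param probes Probe data.frame with a `weight` column.
#' @param n_jobs Number of jobs N (>= 1).
#' @return A `job_partition`: `jobs` (list of N probe data.frames, each in
#'   assignment order), `loads`, `mean_load`, `assignment` (job index per
#'   input row).
#' @examples
#' p <- data.frame(weight = c(4, 3, 3, 2))
#' worst_fit_partition(p, 2)$loads  # 6 6
#' @export
worst_fit_partition <- function(probes, n_jobs) {
    stopifnot(is.data.frame(probes), "weight" %in% names(probes))
    n_jobs <- as.integer(n_jobs)
    if (is.na(n_jobs) || n_jobs < 1L)
        stop("n_jobs must be a positive integer", call. = FALSE)
    ord <- order(-probes$weight, method = "radix")          # stable: equal weights keep order
    loads <- numeric(n_jobs)
    assignment <- integer(nrow(probes))
    job_rows <- vector("list", n_jobs)
    for (j in seq_len(n_jobs)) job_rows[[j]] <- integer(0)
    for (i in ord) {
        j <- which.min(loads)             # lowest index on ties
        assignment[i] <- j
        loads[j] <- loads[j] + probes$weight[i]
        job_rows[[j]] <- c(job_rows[[j]], i)
    }
    jobs <- lapply(job_rows, function(ix) probes[ix, , drop = FALSE])
    structure(list(jobs = jobs, loads = loads,
                   mean_load = sum(probes$weight) / n_jobs,
                   assignment = assignment, n_jobs = n_jobs),
              class = "job_partition")
}

#' @export
print.job_partition <- function(x, ...) {
    st <- load_stats(x$loads)
    cat(sprintf(paste0("<job_partition> %d job(s), %d probe(s); ",
                       "mean load %.2f, load sd %.3f\n"),
                x$n_jobs, length(x$assignment), st$mean, st$sample_std))
    invisible(x)
}

#' Mean and sample standard deviation of per-job loads
#'
#' The dispersion of job loads measures how evenly the screening workload
#' is balanced.  The standard deviation uses the sample (n - 1)
#' denominator; a single job has standard deviation 0 by definition.
#'
#' @param loads Numeric vector of per-job loads (length >= 1).
#' @return A `load_stats` list with `mean` and `sample_std`.
#' @examples
#' load_stats(c(37133, 37132, 37132, 37132))  # mean 37132.25, sd 0.5
#' @export
load_stats <- function(loads) {
    if (length(loads) == 0L) stop("empty load vector", call. = FALSE)
    structure(list(mean = mean(loads),
                   sample_std = if (length(loads) == 1L) 0 else sd(loads)),
              class = "load_stats")
}

#' @export
print.load_stats <- function(x, ...) {
    cat(sprintf("<load_stats> mean %.4g, sample sd %.6g\n",
                x$mean, x$sample_std))
    invisible(x)
}

#' Write per-job probe subfiles and a partition manifest
#'
#' @param partition A `job_partition`.
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_job_files <- function(partition, dir) {
    stopifnot(inherits(partition, "job_partition"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (j in seq_len(partition$n_jobs))
        write_probes(partition$jobs[[j]],
                     file.path(dir, sprintf("job_%03d.tsv", j)))
    st <- load_stats(partition$loads)
    jsonlite::write_json(
        list(n_jobs = partition$n_jobs, loads = partition$loads,
             mean_load = partition$mean_load,
             load_sd = st$sample_std),
        file.path(dir, "partition.json"), auto_unbox = TRUE, digits = NA)
    invisible(dir)
}

# canonical result ordering: parallel execution must not change science,
# so merged outputs are sorted on a fixed key set before writing
.canonical_sort <- function(df) {
    keys <- intersect(c("taxon", "start", "sequence", "expansion",
                        "probe_expansion", "subject_id", "strand",
                        "position"), names(df))
    if (length(keys) == 0L || nrow(df) == 0L) return(df)
    df <- df[do.call(order, c(unname(df[keys]), list(method = "radix"))), ,
             drop = FALSE]
    rownames(df) <- NULL
    df
}

#' Execute partitioned jobs locally, with retry and deterministic merge
#'
#' Runs `worker` on each job's probe table (optionally on a fork-based
#' process pool), retrying a failed job up to `max_retries` times.  When a
#' job exhausts its retries the run aborts with an error carrying the
#' partial manifest.  Results are merged and canonically sorted, so the
#' merged output is identical whatever N was: parallelization never
#' changes the science.
#'
#' @param partition A `job_partition`.
#' @param worker Function of one job's probe data.frame, returning a
#'   data.frame or a named list of data.frames (e.g. [screen_probes()]).
#' @param max_retries Retries allowed per job after the first attempt
#'   (default 2).
#' @param cores Worker processes (default 1 = serial; >1 uses
#'   `parallel::mclapply`).
#' @return List with `results` (merged worker output) and `manifest`
#'   (data.frame: job, state, attempts).
#' @export
run_jobs_local <- function(partition, worker, max_retries = 2L,
                           cores = 1L) {
    stopifnot(inherits(partition, "job_partition"), is.function(worker))
    run_one <- function(j) {
        attempts <- 0L
        out <- NULL
        err <- NULL
        while (attempts <= max_retries) {
            attempts <- attempts + 1L
            out <- tryCatch(worker(partition$jobs[[j]]),
                            error = function(e) structure(
                                list(message = conditionMessage(e)),
                                class = "degenprobe_worker_error"))
            if (!inherits(out, "degenprobe_worker_error")) {
                err <- NULL
                break
            }
            err <- out$message
            out <- NULL
        }
        list(job = j, attempts = attempts,
             state = if (is.null(err)) "done" else "failed",
             error = err, value = out)
    }
    runs <- if (cores > 1L)
        parallel::mclapply(seq_len(partition$n_jobs), run_one,
                           mc.cores = cores)
    else lapply(seq_len(partition$n_jobs), run_one)

    manifest <- data.frame(
        job = vapply(runs, `[[`, integer(1), "job"),
        state = vapply(runs, `[[`, character(1), "state"),
        attempts = vapply(runs, `[[`, integer(1), "attempts"),
        stringsAsFactors = FALSE)
    if (any(manifest$state == "failed")) {
        cond <- simpleError(sprintf(
            "job(s) %s failed after %d attempt(s) each",
            paste(manifest$job[manifest$state == "failed"],
                  collapse = ", "), max_retries + 1L))
        cond$manifest <- manifest
        cond$partial <- lapply(runs[manifest$state == "done"], `[[`,
                               "value")
        class(cond) <- c("degenprobe_job_failure", class(cond))
        stop(cond)
    }

    values <- lapply(runs, `[[`, "value")
    merged <- if (is.data.frame(values[[1L]]))
        .canonical_sort(do.call(rbind, values))
    else {
        parts <- names(values[[1L]])
        out <- lapply(parts, function(p)
            .canonical_sort(do.call(rbind, lapply(values, `[[`, p))))
        names(out) <- parts
        out
    }
    list(results = merged, manifest = manifest)
}
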