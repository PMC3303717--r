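#' @title Job control: indexed entries, states, checkpoints, recovery
#' @description Indexes flat-file entries into jobs carrying their seek
#'   offsets and GI number, dispatches them through the
#'   ready -> pending -> loaded state machine, persists progress to an
#'   append-friendly journal next to a snapshot file, and recovers from
#'   failures: pending jobs left behind by a crashed worker are returned to
#'   ready by an explicit reset, and completed work is never re-dispatched.
#' @name job-control
NULL

#' Build (or upgrade) a job ledger from flat files
#'
#' One ready job per indexed entry.  When a ledger already exists at
#' `ledger_path`, states of previously loaded jobs are preserved — this is
#' the upgrade path for loading entries added by a new release of the same
#' files.  Duplicate GI numbers across files are rejected.
#'
#' @param flat_file_paths character vector of flat file paths.
#' @param ledger_path persistence path for the ledger snapshot; a journal
#'   is kept at `<ledger_path>.journal`.
#' @return a `job_ledger` object.
#' @export
job_build_ledger <- function(flat_file_paths, ledger_path) {
  jobs <- do.call(rbind, c(
    list(data.frame(gi = integer(0), file = character(0),
                    header_offset = integer(0), sequence_offset = integer(0),
                    state = character(0))),
    lapply(flat_file_paths, function(p) {
      idx <- gb_index_entries(p)
      if (nrow(idx) == 0L) return(NULL)
      data.frame(gi = idx$gi, file = p, header_offset = idx$header_offset,
                 sequence_offset = idx$sequence_offset, state = "ready",
                 stringsAsFactors = FALSE)
    })))
  if (anyDuplicated(jobs$gi))
    stop("duplicate GI numbers across input files: ",
         paste(unique(jobs$gi[duplicated(jobs$gi)]), collapse = ", "))
  if (file.exists(ledger_path)) {
    old <- job_open_ledger(ledger_path)
    keep <- old$jobs$gi[old$jobs$state == "loaded"]
    jobs$state[jobs$gi %in% keep] <- "loaded"
  }
  ledger <- new.env(parent = emptyenv())
  ledger$jobs <- jobs
  ledger$path <- ledger_path
  class(ledger) <- "job_ledger"
  job_checkpoint(ledger)
  ledger
}

journal_path <- function(ledger) paste0(ledger$path, ".journal")

#' Open an existing ledger from its snapshot and journal
#'
#' The on-disk state is the snapshot plus the replayed journal of state
#' transitions recorded since the last checkpoint; loaded jobs never
#' revert.
#'
#' @param ledger_path ledger snapshot path.
#' @return a `job_ledger` object.
#' @export
job_open_ledger <- function(ledger_path) {
  if (!file.exists(ledger_path))
    stop("no job ledger at ", ledger_path)
  jobs <- utils::read.delim(ledger_path, stringsAsFactors = FALSE)
  jp <- paste0(ledger_path, ".journal")
  if (file.exists(jp)) {
    for (ln in readLines(jp, warn = FALSE)) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(parts) != 2L) next
      i <- which(jobs$gi == as.integer(parts[2]))
      if (length(i) == 1L && jobs$state[i] != "loaded")
        jobs$state[i] <- switch(parts[1], P = "pending", L = "loaded",
                                jobs$state[i])
    }
  }
  ledger <- new.env(parent = emptyenv())
  ledger$jobs <- jobs
  ledger$path <- ledger_path
  class(ledger) <- "job_ledger"
  ledger
}

journal_append <- function(ledger, code, gi) {
  cat(sprintf("%s\t%d\n", code, gi), file = journal_path(ledger), append = TRUE)
}

#' Dispatch the next ready job
#'
#' The returned job is atomically moved ready -> pending (and journaled),
#' so repeated callers never receive the same job.
#'
#' @param ledger a `job_ledger`.
#' @return a one-row data.frame job, or NULL when no ready job remains.
#' @export
job_next <- function(ledger) {
  i <- which(ledger$jobs$state == "ready")[1]
  if (is.na(i)) return(NULL)
  ledger$jobs$state[i] <- "pending"
  journal_append(ledger, "P", ledger$jobs$gi[i])
  ledger$jobs[i, , drop = FALSE]
}

#' Mark a pending job as loaded
#'
#' Acknowledged only after the transition is durably journaled.  Completing
#' an already loaded job is acknowledged silently (duplicate "completed"
#' messages are tolerated); completing a ready job that was never
#' dispatched is a state error.
#'
#' @param ledger a `job_ledger`.
#' @param gi the job's GI number.
#' @return invisibly TRUE.
#' @export
job_complete <- function(ledger, gi) {
  i <- which(ledger$jobs$gi == gi)
  if (length(i) != 1L) stop("unknown job gi ", gi)
  st <- ledger$jobs$state[i]
  if (st == "loaded") return(invisible(TRUE))  # idempotent acknowledge
  if (st != "pending")
    stop("job state error: cannot complete job gi ", gi, " in state ", st)
  journal_append(ledger, "L", gi)
  ledger$jobs$state[i] <- "loaded"
  invisible(TRUE)
}

#' Write a durable snapshot of the ledger
#'
#' The snapshot is written to a temporary file and atomically renamed over
#' the ledger path, then the journal is truncated.  A crash between
#' checkpoints therefore replays at most the journaled transitions.
#'
#' @param ledger a `job_ledger`.
#' @return invisibly the ledger path.
#' @export
job_checkpoint <- function(ledger) {
  tmp <- paste0(ledger$path, ".tmp")
  utils::write.table(ledger$jobs, tmp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  file.rename(tmp, ledger$path)
  if (file.exists(journal_path(ledger))) file.remove(journal_path(ledger))
  invisible(ledger$path)
}

#' Return all pending jobs to the ready state
#'
#' Recovery step after a worker failure: jobs stuck in pending (dispatched
#' but never completed) become dispatchable again.  Loaded jobs are
#' untouched.  The caller asserts that no worker is active.
#'
#' @param ledger a `job_ledger`.
#' @return number of jobs reset.
#' @export
job_reset_pending <- function(ledger) {
  i <- which(ledger$jobs$state == "pending")
  ledger$jobs$state[i] <- "ready"
  job_checkpoint(ledger)
  length(i)
}

#' Ready/pending/loaded counts of a ledger
#' @param ledger a `job_ledger`.
#' @return named integer vector.
#' @export
job_status <- function(ledger) {
  c(ready = sum(ledger$jobs$state == "ready"),
    pending = sum(ledger$jobs$state == "pending"),
    loaded = sum(ledger$jobs$state == "loaded"))
}

#' @export
print.job_ledger <- function(x, ...) {
  st <- job_status(x)
  cat("job ledger at ", x$path, ": ", st["ready"], " ready, ",
      st["pending"], " pending, ", st["loaded"], " loaded\n", sep = "")
  invisible(x)
}
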