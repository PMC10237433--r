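#' Build and validate a trial table
#'
#' A trial table is the lingua franca of the pipeline: one row per trial
#' with a subject identifier, 1-based trial index, cue condition (1..4),
#' emitted action (1 = go, 0 = no-go) and feedback (-1, 0, +1). Validation
#' enforces the task's structural invariants: values in range, feedback
#' consistent with the cue's domain (reward cues never yield -1, punishment
#' cues never yield +1), and per-subject trial indices strictly increasing
#' and gap-free from 1.
#'
#' @param subject character vector of subject ids.
#' @param trial integer trial index within subject (1-based).
#' @param cue cue condition id, 1..4 (see [cue_conditions]).
#' @param action 1 = go, 0 = no-go.
#' @param feedback -1, 0 or +1.
#' @return A `trial_table` (a data frame with columns `subjID`, `trial`,
#'   `cue`, `keyPressed`, `outcome`), subjects kept in first-appearance
#'   order.
#' @export
trial_table <- function(subject, trial, cue, action, feedback) {
  x <- data.frame(subjID = as.character(subject),
                  trial = as.integer(trial),
                  cue = as.integer(cue),
                  keyPressed = as.integer(action),
                  outcome = as.integer(feedback),
                  stringsAsFactors = FALSE)
  validate_trials(x)
}

#' @rdname trial_table
#' @param x a data frame with the trial-table columns.
#' @export
validate_trials <- function(x) {
  need <- c("subjID", "trial", "cue", "keyPressed", "outcome")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("trial table is missing column(s): ", paste(miss, collapse = ", "))
  if (anyNA(x[need]))
    stop("trial table contains missing values in row(s) ",
         paste(which(rowSums(is.na(x[need])) > 0), collapse = ", "))
  bad <- which(!(x$cue %in% 1:4))
  if (length(bad))
    stop("cue outside 1-4 in row(s) ", paste(bad, collapse = ", "))
  bad <- which(!(x$keyPressed %in% 0:1))
  if (length(bad))
    stop("action (keyPressed) outside {0,1} in row(s) ",
         paste(bad, collapse = ", "))
  bad <- which(!(x$outcome %in% c(-1L, 0L, 1L)))
  if (length(bad))
    stop("feedback (outcome) outside {-1,0,1} in row(s) ",
         paste(bad, collapse = ", "))
  dom <- cue_domain(x$cue)
  bad <- which((dom == "reward" & x$outcome == -1L) |
               (dom == "punishment" & x$outcome == 1L))
  if (length(bad))
    stop("feedback inconsistent with cue domain in row(s) ",
         paste(bad, collapse = ", "),
         " (reward cues yield {0,+1}, punishment cues {-1,0})")
  for (id in unique(x$subjID)) {
    tr <- x$trial[x$subjID == id]
    if (length(tr) && !identical(as.integer(tr), seq_along(tr)))
      stop("trial indices for subject '", id,
           "' are not strictly increasing and gap-free from 1")
  }
  class(x) <- unique(c("trial_table", class(x)))
  x
}

#' @export
print.trial_table <- function(x, ...) {
  cat("Trial table:", length(unique(x$subjID)), "subject(s),",
      nrow(x), "trials\n")
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Read and write trial tables
#'
#' Trial tables are stored as plain CSV/TSV with a header, one row per
#' trial. The default column names (`subjID`, `trial`, `cue`, `keyPressed`,
#' `outcome`) follow a widely used go/no-go convention; other dialects are
#' remapped via `dialect`, a named character vector mapping canonical names
#' to the file's column names. A missing `trial` column is reconstructed
#' from row order within subject.
#'
#' @param path file path.
#' @param dialect named character vector, e.g.
#'   `c(subjID = "participant", cue = "condition")`; unnamed canonical
#'   columns are looked up under their own names.
#' @param sep field separator; `","` (default) or `"\t"`.
#' @return `read_trials()` returns a validated `trial_table`;
#'   `write_trials()` invisibly returns `path`.
#' @export
read_trials <- function(path, dialect = character(), sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE)
  canon <- c("subjID", "trial", "cue", "keyPressed", "outcome")
  cols <- stats::setNames(canon, canon)
  cols[names(dialect)] <- dialect
  miss <- canon[!(cols %in% names(raw)) & canon != "trial"]
  if (length(miss))
    stop("cannot resolve column(s) ", paste(miss, collapse = ", "),
         " in ", path)
  x <- data.frame(subjID = as.character(raw[[cols["subjID"]]]),
                  stringsAsFactors = FALSE)
  if (cols["trial"] %in% names(raw)) {
    x$trial <- as.integer(raw[[cols["trial"]]])
  } else {
    x$trial <- stats::ave(seq_len(nrow(raw)), raw[[cols["subjID"]]],
                          FUN = seq_along)
  }
  x$cue <- as.integer(raw[[cols["cue"]]])
  x$keyPressed <- as.integer(raw[[cols["keyPressed"]]])
  x$outcome <- as.integer(raw[[cols["outcome"]]])
  validate_trials(x)
}

#' @rdname read_trials
#' @param table a `trial_table`.
#' @export
write_trials <- function(table, path, sep = ",") {
  table <- validate_trials(table)
  utils::write.table(as.data.frame(table)[, c("subjID", "trial", "cue",
                                              "keyPressed", "outcome")],
                     path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Exclude subjects who failed to learn the easiest condition
#'
#' Subjects whose proportion of go responses on go-to-win cues (the
#' Pavlovian-congruent reward condition, where learning is easiest) falls
#' strictly below `threshold` are removed; failure there indicates a lack
#' of task understanding or engagement rather than a bias of interest.
#'
#' @param table a `trial_table`.
#' @param threshold exclusion threshold on go-to-win accuracy (default 0.1,
#'   exclusion is strict `<`).
#' @return A list with `table` (the retained subjects, order preserved),
#'   `excluded` (character vector of removed ids) and `accuracy` (named
#'   go-to-win accuracy for every input subject).
#' @export
apply_exclusions <- function(table, threshold = 0.1) {
  stopifnot(threshold >= 0, threshold <= 1)
  table <- validate_trials(table)
  ids <- unique(table$subjID)
  acc <- vapply(ids, function(id) {
    rows <- table$subjID == id & table$cue == 1L
    if (!any(rows))
      stop("subject '", id,
           "' has no go-to-win trials; exclusion accuracy undefined")
    mean(table$keyPressed[rows] == 1L)
  }, numeric(1))
  excluded <- ids[acc < threshold]
  out <- table[!(table$subjID %in% excluded), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(table)
  list(table = out, excluded = excluded, accuracy = acc)
}
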