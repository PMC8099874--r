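#' Scripted assessment tasks
#'
#' Each tremor assessment records seven scripted tasks: two rest positions
#' (forearm on lap / on a table), two postural positions (outstretched arms,
#' hands facing down / facing each other), two weight-bearing tasks (empty
#' cup / 1-lb weighted cup) and a kinetic finger-to-nose task. The kinetic
#' task mixes voluntary motion into the recording and is excluded from the
#' classification pipeline; the six static tasks carry a fixed hint index
#' 0..5 used for the network's one-hot task hint.
#'
#' @return `task_levels()` returns the 7 canonical task names;
#'   `included_tasks()` the 6 static tasks in hint-index order.
#' @export
task_levels <- function() {
  c("Rest1", "Rest2", "Posture1", "Posture2", "Load1", "Load2",
    "FingerToNose")
}

#' @rdname task_levels
#' @export
included_tasks <- function() task_levels()[1:6]

#' @rdname task_levels
#' @export
axis_levels <- function() c("x", "y", "z")

hand_levels <- function() c("left", "right")
group_levels <- function() c("PD", "ET", "unknown")

#' Is a task excluded from the pipeline?
#'
#' Only the kinetic finger-to-nose task is excluded: it superimposes
#' voluntary movement on the tremor and is dropped before any processing.
#'
#' @param task character vector of canonical task names.
#' @return logical vector.
#' @export
task_excluded <- function(task) {
  task <- canonical_task(task)
  task == "FingerToNose"
}

#' Hint index of an included task
#'
#' @param task canonical task name(s); the excluded finger-to-nose task is
#'   rejected.
#' @return integer 0-based hint index (Rest1=0 ... Load2=5).
#' @export
task_hint_index <- function(task) {
  task <- canonical_task(task)
  if (any(task == "FingerToNose")) {
    stop("FingerToNose is excluded from the pipeline and has no hint index")
  }
  match(task, included_tasks()) - 1L
}

# Case-insensitive canonicalisation of task / axis / hand / group strings.
# Hyphens and underscores are ignored so hand-edited manifests with e.g.
# "rest-1" still parse.
canonical_match <- function(x, levels, what) {
  key <- tolower(gsub("[-_ ]", "", as.character(x)))
  ref <- tolower(gsub("[-_ ]", "", levels))
  i <- match(key, ref)
  if (anyNA(i)) {
    bad <- unique(as.character(x)[is.na(i)])
    stop(sprintf("unknown %s value(s): %s", what,
                 paste(bad, collapse = ", ")))
  }
  levels[i]
}

#' @rdname task_excluded
#' @export
canonical_task <- function(task) canonical_match(task, task_levels(), "task")

canonical_axis <- function(axis) canonical_match(axis, axis_levels(), "axis")
canonical_hand <- function(hand) canonical_match(hand, hand_levels(), "hand")
canonical_group <- function(group) {
  canonical_match(group, group_levels(), "group")
}

#' Canonical position of a feature in the 54-vector
#'
#' Stage two sees one feature per (trial, task, axis) combination, ordered
#' trial-major: index = (trial-1)*18 + hint_index(task)*3 + axis_index,
#' 0-based. `feature_index()` returns that 0-based index;
#' `feature_order()` enumerates all 54 combinations in canonical order
#' together with their display labels.
#'
#' @param trial trial number in 1..3.
#' @param task included task name.
#' @param axis axis name ("x", "y" or "z").
#' @return 0-based integer index in 0..53.
#' @export
feature_index <- function(trial, task, axis) {
  trial <- as.integer(trial)
  if (any(is.na(trial) | trial < 1L | trial > 3L)) {
    stop("trial must be in 1..3")
  }
  ax <- match(canonical_axis(axis), axis_levels()) - 1L
  (trial - 1L) * 18L + task_hint_index(task) * 3L + ax
}

#' @rdname feature_index
#' @export
feature_label <- function(trial, task, axis) {
  sprintf("%d-%s-%s", as.integer(trial), canonical_task(task),
          canonical_axis(axis))
}

#' @rdname feature_index
#' @export
feature_order <- function() {
  grid <- expand.grid(axis = axis_levels(), task = included_tasks(),
                      trial = 1:3, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("trial", "task", "axis")]
  grid$index <- feature_index(grid$trial, grid$task, grid$axis)
  grid$label <- feature_label(grid$trial, grid$task, grid$axis)
  stopifnot(identical(grid$index, 0:53))
  grid
}
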