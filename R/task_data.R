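# Visible-layer layout ---------------------------------------------------
#
# The visible layer concatenates five channels, in this fixed order:
#   red map (25x25 = 625), green map (625), context A (25), context B (25),
#   action map (625)  -> 1925 units total.
# Grid coordinates are 0-based and row-major within each 25x25 map; indices
# into the visible vector are 1-based (R convention).

#' Visible-layer channel offsets and sizes
#'
#' Constants describing the 1925-unit visible layer: two 25x25 colour maps,
#' two 25-unit context blocks and one 25x25 action map.
#'
#' @format A named integer vector of 0-based channel offsets.
#' @keywords internal
#' @export
channel_offsets <- c(
  red = 0L, green = 625L, context_a = 1250L, context_b = 1275L, action = 1300L
)

#' @rdname channel_offsets
#' @export
channel_sizes <- c(
  red = 625L, green = 625L, context_a = 25L, context_b = 25L, action = 625L
)

#' @rdname channel_offsets
#' @export
n_visible_units <- 1925L

grid_side <- 25L
square_side <- 5L
max_corner <- grid_side - square_side # 20: largest valid top-left coordinate

#' Construct a grid position (top-left corner of a 5x5 square)
#'
#' @param row,col 0-based coordinates of the square's top-left corner inside
#'   the 25x25 grid. Both must lie in 0..20 so the 5x5 footprint stays inside
#'   the grid.
#' @return An object of class `grid_position`.
#' @export
grid_position <- function(row, col) {
  row <- as.integer(row); col <- as.integer(col)
  if (length(row) != 1L || is.na(row) || row < 0L || row > max_corner)
    stop("invalid row ", row, ": must be an integer in 0..", max_corner)
  if (length(col) != 1L || is.na(col) || col < 0L || col > max_corner)
    stop("invalid col ", col, ": must be an integer in 0..", max_corner)
  structure(list(row = row, col = col), class = "grid_position")
}

#' @export
print.grid_position <- function(x, ...) {
  cat(sprintf("grid_position(row = %d, col = %d)\n", x$row, x$col))
  invisible(x)
}

#' @export
format.grid_position <- function(x, ...) sprintf("(%d,%d)", x$row, x$col)

#' Visible-vector indices of a 5x5 square in a given channel
#'
#' Maps a grid position to the 25 (1-based) indices of its footprint inside
#' the requested channel's segment of the 1925-unit visible vector.
#'
#' @param pos A [grid_position()].
#' @param channel One of `"red"`, `"green"`, `"action"`.
#' @return Integer vector of 25 indices.
#' @export
square_indices <- function(pos, channel = c("red", "green", "action")) {
  channel <- match.arg(channel)
  if (!inherits(pos, "grid_position")) pos <- grid_position(pos$row, pos$col)
  rows <- pos$row + 0:(square_side - 1L)
  cols <- pos$col + 0:(square_side - 1L)
  flat0 <- as.integer(outer(rows * grid_side, cols, "+")) # 0-based in-map
  sort(flat0) + channel_offsets[[channel]] + 1L
}

positions_overlap <- function(a, b) {
  abs(a$row - b$row) < square_side && abs(a$col - b$col) < square_side
}

sample_position <- function() {
  grid_position(
    sample.int(max_corner + 1L, 1L) - 1L,
    sample.int(max_corner + 1L, 1L) - 1L
  )
}

# The two admissible corners of the restricted-variability control.
corner_positions <- function() {
  list(top_left = grid_position(0L, 0L),
       bottom_right = grid_position(max_corner, max_corner))
}

#' Sample a trial description
#'
#' Draws one trial: stimulus position(s), context, and the implied action.
#' A single-stimulus trial always pairs the stimulus colour with its matching
#' context (red with context A, green with context B), so the presented
#' stimulus is the relevant one and the action targets it. In double-stimulus
#' trials the two 5x5 footprints are kept spatially disjoint by rejection
#' sampling. In `two_locations` mode positions are drawn only from the
#' top-left and bottom-right corners (double-stimulus trials occupy the two
#' different corners).
#'
#' Uses R's global random-number stream; call `set.seed()` for
#' reproducibility.
#'
#' @param two_stimuli Logical: present both the red and the green square?
#' @param context `"A"` (red relevant) or `"B"` (green relevant).
#' @param two_locations Logical: restrict positions to the two corners.
#' @param action_present Logical: is the action part of the pattern?
#' @return An object of class `pattern_spec` with fields `red_pos`,
#'   `green_pos` (either may be `NULL`), `context`, `action_present` and the
#'   derived `action_pos` (position of the context-relevant stimulus).
#' @export
sample_spec <- function(two_stimuli, context = c("A", "B"),
                        two_locations = FALSE, action_present = TRUE) {
  context <- match.arg(context)
  if (two_locations) {
    corners <- corner_positions()
    if (two_stimuli) {
      red_first <- sample.int(2L, 1L) == 1L
      red_pos <- if (red_first) corners$top_left else corners$bottom_right
      green_pos <- if (red_first) corners$bottom_right else corners$top_left
    } else {
      pos <- corners[[sample.int(2L, 1L)]]
      red_pos <- if (context == "A") pos else NULL
      green_pos <- if (context == "B") pos else NULL
    }
  } else if (two_stimuli) {
    repeat {
      red_pos <- sample_position()
      green_pos <- sample_position()
      if (!positions_overlap(red_pos, green_pos)) break
    }
  } else {
    red_pos <- if (context == "A") sample_position() else NULL
    green_pos <- if (context == "B") sample_position() else NULL
  }
  pattern_spec(red_pos, green_pos, context, action_present)
}

#' @rdname sample_spec
#' @param red_pos,green_pos [grid_position()] or `NULL` (absent stimulus).
#' @export
pattern_spec <- function(red_pos, green_pos, context = c("A", "B"),
                         action_present = TRUE) {
  context <- match.arg(context)
  if (is.null(red_pos) && is.null(green_pos))
    stop("a pattern must contain at least one stimulus")
  if (context == "A" && is.null(red_pos))
    stop("context A requires the red (relevant) stimulus to be present")
  if (context == "B" && is.null(green_pos))
    stop("context B requires the green (relevant) stimulus to be present")
  if (!is.null(red_pos) && !is.null(green_pos) &&
      positions_overlap(red_pos, green_pos))
    stop("red and green footprints overlap")
  action_pos <- if (context == "A") red_pos else green_pos
  structure(
    list(red_pos = red_pos, green_pos = green_pos, context = context,
         action_present = isTRUE(action_present), action_pos = action_pos),
    class = "pattern_spec"
  )
}

#' @export
print.pattern_spec <- function(x, ...) {
  fmt <- function(p) if (is.null(p)) "absent" else format(p)
  cat(sprintf(
    "pattern_spec: red %s, green %s, context %s, action %s at %s\n",
    fmt(x$red_pos), fmt(x$green_pos), x$context,
    if (x$action_present) "present" else "absent", fmt(x$action_pos)
  ))
  invisible(x)
}

is_double_stimulus <- function(spec) {
  !is.null(spec$red_pos) && !is.null(spec$green_pos)
}

#' Render a trial description to a 1925-unit visible vector
#'
#' @param spec A [pattern_spec()].
#' @param include_action Logical: write the action square? `FALSE` implements
#'   the no-action-input test condition (action channel all zero).
#' @return Numeric vector of length 1925 with values in \{0, 1\}.
#' @export
render <- function(spec, include_action = spec$action_present) {
  v <- numeric(n_visible_units)
  if (!is.null(spec$red_pos)) v[square_indices(spec$red_pos, "red")] <- 1
  if (!is.null(spec$green_pos)) v[square_indices(spec$green_pos, "green")] <- 1
  ctx <- if (spec$context == "A") "context_a" else "context_b"
  v[channel_offsets[[ctx]] + seq_len(channel_sizes[[ctx]])] <- 1
  if (include_action) v[square_indices(spec$action_pos, "action")] <- 1
  v
}

render_all <- function(specs, include_action = TRUE) {
  V <- matrix(0, nrow = length(specs), ncol = n_visible_units)
  for (i in seq_along(specs)) V[i, ] <- render(specs[[i]], include_action)
  V
}

new_dataset <- function(specs, V, condition) {
  structure(list(specs = specs, V = V, condition = condition,
                 n = length(specs)),
            class = "attnet_dataset")
}

#' @export
print.attnet_dataset <- function(x, ...) {
  nd <- sum(vapply(x$specs, is_double_stimulus, logical(1)))
  cat(sprintf(
    "attnet_dataset: %d patterns (%d single, %d double stimulus), condition '%s'\n",
    x$n, x$n - nd, nd, x$condition
  ))
  invisible(x)
}

#' Generate the training dataset
#'
#' Builds `n` training patterns: half single-stimulus (the context-matching
#' colour only, with its action) and half double-stimulus, with contexts A
#' and B each occurring in exactly half of each group. All training patterns
#' include the action input. Pattern order is randomised.
#'
#' @param n Number of patterns (default 5000).
#' @param two_locations Restrict stimulus positions to the two corners.
#' @param double_only If `TRUE`, all patterns contain both stimuli (the
#'   training-set-variation control).
#' @return An `attnet_dataset` with fields `specs` (list of `pattern_spec`)
#'   and `V` (`n` x 1925 numeric matrix).
#' @export
generate_training_set <- function(n = 5000L, two_locations = FALSE,
                                  double_only = FALSE) {
  n <- as.integer(n)
  stopifnot(n >= 4L, n %% 4L == 0L)
  two_flags <- if (double_only) rep(TRUE, n) else rep(c(FALSE, TRUE), each = n / 2L)
  contexts <- rep(rep(c("A", "B"), each = n / 4L), 2L)
  if (double_only) contexts <- rep(c("A", "B"), each = n / 2L)
  ord <- sample.int(n)
  specs <- vector("list", n)
  for (i in seq_len(n)) {
    specs[[i]] <- sample_spec(two_flags[ord[i]], contexts[ord[i]],
                              two_locations = two_locations)
  }
  new_dataset(specs, render_all(specs, include_action = TRUE), "train")
}

#' Generate a test dataset
#'
#' Test patterns always contain both stimuli at random disjoint locations,
#' half in context A and half in context B (so half the actions target the
#' red and half the green square). Under `condition = "no_action"` the action
#' channel of the rendered input is all zero; the trial descriptions still
#' carry the correct action location for evaluation.
#'
#' @param n Number of patterns (default 1000).
#' @param condition `"complete"` or `"no_action"`.
#' @param two_locations Restrict stimulus positions to the two corners.
#' @return An `attnet_dataset`.
#' @export
generate_test_set <- function(n = 1000L,
                              condition = c("complete", "no_action"),
                              two_locations = FALSE) {
  condition <- match.arg(condition)
  n <- as.integer(n)
  stopifnot(n >= 2L, n %% 2L == 0L)
  contexts <- sample(rep(c("A", "B"), each = n / 2L))
  specs <- lapply(contexts, function(ctx)
    sample_spec(TRUE, ctx, two_locations = two_locations))
  new_dataset(specs, render_all(specs, include_action = condition == "complete"),
              condition)
}
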