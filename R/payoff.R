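# Base 10-card block of the modified IGT schedule. Card-by-card amounts of
# the original computerized task are not published; this fixture reproduces
# its documented structure: wins vary around a mean of $100 (decks A, B)
# or $50 (decks C, D); deck A spreads five losses per 10 cards summing to
# -$1250, deck B concentrates one -$1250 loss, deck C five losses summing
# to -$250, deck D one -$250 loss. Net per 10 cards: -$250 for A/B (bad),
# +$250 for C/D (good).
BASE_WINS_AB <- c(90, 100, 110, 95, 105, 100, 90, 110, 95, 105)
BASE_WINS_CD <- c(45, 50, 55, 48, 52, 50, 45, 55, 48, 52)
BASE_LOSSES <- list(
  A = c(0, 0, -150, 0, -200, 0, -250, 0, -300, -350),
  B = c(0, 0, 0, 0, 0, 0, 0, 0, -1250, 0),
  C = c(0, 0, -25, 0, -75, 0, -50, 0, -50, -50),
  D = c(0, 0, 0, 0, 0, 0, 0, 0, 0, -250)
)

#' Build the modified-IGT payoff schedule
#'
#' Four decks (A, B, C, D) of exactly 60 cards each, in six blocks of ten.
#' Block-1 wins average $100 for the disadvantageous decks A and B and $50
#' for the advantageous decks C and D; every 10 cards net -$250 on A/B and
#' +$250 on C/D. All amounts (wins and losses) escalate across blocks by
#' the factor `1 + escalation_rate * (block - 1)`, rounded to whole
#' dollars. The build is fully deterministic.
#'
#' @param escalation_rate Per-block escalation fraction, >= 0. Default 0.1.
#' @return A tibble with columns `deck`, `card` (1-60), `block` (1-6),
#'   `win` (>= 0) and `loss` (<= 0).
#' @examples
#' sched <- payoff_schedule()
#' dplyr::count(sched, deck)
#' @export
payoff_schedule <- function(escalation_rate = 0.1) {
  if (!is.numeric(escalation_rate) || length(escalation_rate) != 1 ||
      !is.finite(escalation_rate) || escalation_rate < 0) {
    abort("`escalation_rate` must be a single non-negative number")
  }
  blocks <- tidyr::expand_grid(deck = DECKS, block = 1:6)
  sched <- purrr::pmap_dfr(blocks, function(deck, block) {
    wins <- if (deck %in% c("A", "B")) BASE_WINS_AB else BASE_WINS_CD
    losses <- BASE_LOSSES[[deck]]
    f <- 1 + escalation_rate * (block - 1)
    tibble::tibble(
      deck = deck,
      card = (block - 1L) * 10L + 1:10,
      block = block,
      win = round(wins * f),
      loss = round(losses * f)
    )
  })
  dplyr::arrange(sched, .data$deck, .data$card)
}

#' Validate a payoff schedule
#'
#' Checks the structural invariants of a schedule: 60 cards per deck with
#' contiguous indices, non-negative wins and non-positive losses, block-1
#' mean wins of $100 (A/B) and $50 (C/D), negative per-10-card net for
#' decks A/B and positive for C/D in every block, and amounts
#' non-decreasing across blocks at the same within-block position.
#'
#' @param schedule A schedule tibble as from [payoff_schedule()].
#' @return The schedule, invisibly; aborts with a message on violation.
#' @export
validate_payoff_schedule <- function(schedule) {
  need <- c("deck", "card", "win", "loss")
  miss <- setdiff(need, names(schedule))
  if (length(miss) > 0)
    abort(paste0("schedule is missing column(s): ", paste(miss, collapse = ", ")))
  counts <- dplyr::count(schedule, .data$deck)
  if (!setequal(counts$deck, DECKS) || any(counts$n != 60))
    abort("each of decks A-D must have exactly 60 cards")
  byd <- dplyr::group_by(schedule, .data$deck)
  ord <- dplyr::summarise(byd, ok = all(sort(.data$card) == 1:60))
  if (!all(ord$ok)) abort("card indices must be 1..60 within each deck")
  if (any(schedule$win < 0) || any(schedule$loss > 0))
    abort("wins must be >= 0 and losses <= 0")
  b1 <- dplyr::filter(schedule, .data$card <= 10)
  m <- dplyr::summarise(dplyr::group_by(b1, .data$deck), m = mean(.data$win))
  target <- c(A = 100, B = 100, C = 50, D = 50)
  if (any(abs(m$m - target[m$deck]) > 1e-9))
    abort("block-1 mean win must be 100 for decks A/B and 50 for C/D")
  nets <- schedule |>
    dplyr::mutate(block = (.data$card - 1) %/% 10 + 1) |>
    dplyr::group_by(.data$deck, .data$block) |>
    dplyr::summarise(net = sum(.data$win + .data$loss), .groups = "drop")
  bad_net <- (nets$deck %in% c("A", "B") & nets$net >= 0) |
    (nets$deck %in% c("C", "D") & nets$net <= 0)
  if (any(bad_net))
    abort("per-10-card net must be negative for decks A/B and positive for C/D")
  mono <- schedule |>
    dplyr::mutate(block = (.data$card - 1) %/% 10 + 1,
                  pos = (.data$card - 1) %% 10 + 1) |>
    dplyr::arrange(.data$deck, .data$pos, .data$block) |>
    dplyr::group_by(.data$deck, .data$pos) |>
    dplyr::summarise(ok = !is.unsorted(.data$win) && !is.unsorted(-.data$loss),
                     .groups = "drop")
  if (!all(mono$ok))
    abort("amounts must be non-decreasing across blocks at the same position")
  invisible(schedule)
}

#' Write / read a payoff schedule as CSV
#'
#' Serialized columns: `deck`, `card`, `win`, `loss`. Reading re-derives
#' the `block` column and validates all schedule invariants.
#'
#' @param schedule A schedule tibble.
#' @param path File path.
#' @return `write_payoff_schedule()` the input invisibly;
#'   `read_payoff_schedule()` a validated schedule tibble.
#' @export
write_payoff_schedule <- function(schedule, path) {
  validate_payoff_schedule(schedule)
  readr::write_csv(schedule[, c("deck", "card", "win", "loss")], path)
  invisible(schedule)
}

#' @rdname write_payoff_schedule
#' @export
read_payoff_schedule <- function(path) {
  sched <- readr::read_csv(path, col_types = readr::cols(
    deck = readr::col_character(), card = readr::col_integer(),
    win = readr::col_double(), loss = readr::col_double()
  ))
  sched$block <- (sched$card - 1L) %/% 10L + 1L
  validate_payoff_schedule(sched)
  sched
}

#' Net outcome of a trial
#'
#' @param win Win amount(s), >= 0.
#' @param loss Loss amount(s), <= 0.
#' @return `win + loss`.
#' @export
net_outcome <- function(win, loss) {
  stopifnot(all(win >= 0), all(loss <= 0))
  win + loss
}
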