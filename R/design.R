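#' Build counterbalanced lists for an old/new blur design
#'
#' Rotates a word pool through the full crossing of study status
#' (old/new) and blur level so that each word serves in every
#' (status, blur) cell exactly once across lists, and every list carries
#' equal item counts per cell. With 3 blur levels and 2 statuses this is
#' the classic six-list scheme: each list holds one study (old) set and
#' one test-only (new) set, each split evenly over blur levels.
#'
#' Mechanically, the pool is shuffled (by `seed`), split into
#' `n_cells = |statuses| * |blur_levels|` equal blocks, and block `g` is
#' assigned to cell `(g + l) mod n_cells` on list `l` — a Latin square
#' over cells, which guarantees both balance invariants.
#'
#' @param n_words total word pool size; must be divisible by
#'   `|statuses| * |blur_levels|`.
#' @param blur_levels character vector of blur conditions
#'   (default `c("clear", "low", "high")`).
#' @param statuses item statuses to rotate (default `c("old", "new")`).
#' @param seed integer; the block shuffle is deterministic given `seed`.
#' @return a tibble with columns `list_id`, `item_id`, `status`, `blur`;
#'   `n_lists = |statuses| * |blur_levels|` lists.
#' @examples
#' lists <- build_counterbalanced_lists(168, seed = 1)
#' dplyr::count(lists, list_id, status, blur)  # 28 per cell
#' @export
build_counterbalanced_lists <- function(n_words,
                                        blur_levels = c("clear", "low", "high"),
                                        statuses = c("old", "new"),
                                        seed = 1) {
  cells <- tidyr::expand_grid(status = statuses, blur = blur_levels)
  n_cells <- nrow(cells)
  if (n_words %% n_cells != 0) {
    abort(sprintf(
      "pool of %d words is not divisible into %d (status x blur) cells of equal size.",
      n_words, n_cells
    ))
  }
  per_cell <- n_words / n_cells
  items <- withr::with_seed(seed, sample(seq_len(n_words)))
  block <- rep(seq_len(n_cells), each = per_cell)  # block of each shuffled item
  purrr::map_dfr(seq_len(n_cells), function(l) {
    cell_of_block <- ((seq_len(n_cells) - 1 + (l - 1)) %% n_cells) + 1
    tibble::tibble(
      list_id = l,
      item_id = paste0("w", items),
      status = cells$status[cell_of_block[block]],
      blur = cells$blur[cell_of_block[block]]
    )
  })
}

#' Build study/test lists for a frequency-by-blur semantic categorisation design
#'
#' Constructs six counterbalanced lists in which `n_nonanimal_study`
#' non-animal target words (split evenly between high- and low-frequency
#' per `frequency_split`) rotate through the (status, blur) cells, while
#' `n_animal` animal filler words appear at study only and never at test
#' (fillers are excluded from all analyses at the design level). The
#' default counts (90 non-animal study words, 45 animal fillers)
#' maintain a 2:1 non-animal:animal study ratio.
#'
#' @param n_nonanimal_study number of non-animal words studied per list
#'   (must split evenly over frequency and blur cells).
#' @param n_animal number of animal filler words at study.
#' @param frequency_split proportion of study words that are
#'   high-frequency (default 0.5; only 0.5 yields the even split the
#'   rotation requires).
#' @param blur_levels blur conditions.
#' @param seed integer shuffle seed.
#' @return a tibble with columns `list_id`, `item_id`, `status`
#'   (`old`/`new` for non-animal words, `filler` for animals), `blur`,
#'   `frequency`, `stim_class`.
#' @export
build_exp2_study_list <- function(n_nonanimal_study = 90, n_animal = 45,
                                  frequency_split = 0.5,
                                  blur_levels = c("clear", "low", "high"),
                                  seed = 1) {
  n_freq_hi <- n_nonanimal_study * frequency_split
  if (n_freq_hi != round(n_freq_hi)) {
    abort("`n_nonanimal_study * frequency_split` must be an integer (even frequency split).")
  }
  n_cells <- 2 * length(blur_levels)
  if (n_nonanimal_study %% (length(blur_levels) * 2) != 0) {
    abort(sprintf(
      "%d non-animal study words do not divide into %d (blur x frequency) study cells.",
      n_nonanimal_study, length(blur_levels) * 2
    ))
  }
  # rotate each frequency stratum independently over (status x blur)
  pool_per_freq <- n_nonanimal_study  # study + matched new set, per frequency: half each
  freq_lists <- purrr::imap_dfr(
    c(high = 0L, low = 1L),
    function(offset, freq) {
      lists <- withr::with_seed(
        seed + offset,
        build_counterbalanced_lists(pool_per_freq, blur_levels,
                                    statuses = c("old", "new"),
                                    seed = seed + offset)
      )
      lists$item_id <- paste0(substr(freq, 1, 1), "f_", lists$item_id)
      lists$frequency <- freq
      lists
    }
  )
  freq_lists$stim_class <- "nonanimal"
  n_lists <- length(unique(freq_lists$list_id))
  animals <- if (n_animal > 0) {
    blur_assign <- rep_len(blur_levels, n_animal)
    purrr::map_dfr(seq_len(n_lists), function(l) {
      # rotate filler blur across lists too, so fillers are balanced per list
      shift <- ((seq_along(blur_assign) + l - 2) %% length(blur_levels)) + 1
      tibble::tibble(
        list_id = l,
        item_id = paste0("animal_", seq_len(n_animal)),
        status = "filler",
        blur = blur_levels[shift],
        frequency = "none",
        stim_class = "animal"
      )
    })
  } else {
    NULL
  }
  dplyr::bind_rows(freq_lists, animals) |>
    dplyr::arrange(.data$list_id, .data$item_id)
}

#' Allocate participants evenly across counterbalance lists
#'
#' @param lists a list tibble from [build_counterbalanced_lists()] (or a
#'   vector of list ids).
#' @param n_per_list number of subjects per list.
#' @return a tibble `subject_id`, `list_id` with
#'   `n_lists * n_per_list` rows.
#' @export
assign_participants <- function(lists, n_per_list) {
  if (n_per_list < 1) abort("`n_per_list` must be at least 1.")
  ids <- if (is.data.frame(lists)) sort(unique(lists$list_id)) else sort(unique(lists))
  tidyr::expand_grid(list_id = ids, idx = seq_len(n_per_list)) |>
    dplyr::mutate(subject_id = sprintf("s%02d_%03d", .data$list_id, .data$idx)) |>
    dplyr::select("subject_id", "list_id")
}
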