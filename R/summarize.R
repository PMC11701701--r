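#' Summarize a result table
#'
#' Counts the lines and distinct activity IDs of a search result, breaks
#' the activities down by class letter and by functional role
#' (hydrolase, phosphorylase, transglycosylase, mutase, lyase, oxidase —
#' phosphorylases and transglycosylases share the class letter T and are
#' told apart by their reactant), and tabulates the union of families
#' with the number of distinct activities listing each.
#'
#' @param rt A result table (any activity table).
#' @return A `cazac_summary` object with elements `n_lines`,
#'   `n_activities`, `by_class` (named integer vector), `families`,
#'   `by_family` (tibble with `family` and `n_activities`) and `by_role`
#'   (named integer vector).
#' @examples
#' endo <- run_query(load_fixture(),
#'                   cazac_query(cazy_class = "GH", residue = "aDGlcp",
#'                               strict = TRUE, reac_bond = "1,4"))
#' summarize_results(endo)
#' @export
summarize_results <- function(rt) {
  tb <- as_tibble(rt)
  ids <- distinct_activity_ids(tb)
  letters_by_id <- substr(ids, 1L, 1L)
  by_class <- vapply(c("H", "L", "T", "M", "O"),
                     function(l) sum(letters_by_id == l), integer(1))

  role_of_line <- function(activity_id, reactant) {
    letter <- substr(activity_id, 1L, 1L)
    switch(letter,
      H = "hydrolase", L = "lyase", M = "mutase", O = "oxidase",
      T = if (parse_reactant(reactant)$variant == "phosphate") {
        "phosphorylase"
      } else {
        "transglycosylase"
      }
    )
  }
  roles_by_id <- vapply(ids, function(id) {
    rows <- tb[tb$activity_id == id, ]
    role_of_line(rows$activity_id[[1]], rows$reactant[[1]])
  }, character(1))
  role_levels <- c("hydrolase", "phosphorylase", "transglycosylase",
                   "mutase", "lyase", "oxidase")
  by_role <- vapply(role_levels, function(r) sum(roles_by_id == r), integer(1))

  fams <- families_of(tb)
  by_family <- tibble(
    family = fams,
    n_activities = vapply(fams, function(f) {
      length(unique(tb$activity_id[
        map_lgl(tb$families, function(s) f %in% split_families(s))
      ]))
    }, integer(1), USE.NAMES = FALSE)
  )

  structure(
    list(
      n_lines = nrow(tb),
      n_activities = length(ids),
      activity_ids = ids,
      by_class = by_class,
      families = fams,
      by_family = by_family,
      by_role = by_role
    ),
    class = "cazac_summary"
  )
}

#' @export
print.cazac_summary <- function(x, ...) {
  cat("<cazac_summary>\n")
  cat("  lines:              ", x$n_lines, "\n", sep = "")
  cat("  distinct activities:", x$n_activities, "\n")
  nz <- x$by_class[x$by_class > 0L]
  if (length(nz) > 0L) {
    cat("  by class letter:    ",
        paste(names(nz), nz, sep = "=", collapse = ", "), "\n", sep = "")
  }
  nzr <- x$by_role[x$by_role > 0L]
  if (length(nzr) > 0L) {
    cat("  by role:            ",
        paste(names(nzr), nzr, sep = "=", collapse = ", "), "\n", sep = "")
  }
  cat("  families (", length(x$families), "): ",
      paste(x$families, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tidy a result summary
#'
#' `tidy()` returns the per-family breakdown (one row per family with
#' the number of distinct activities listing it); `glance()` returns a
#' one-row tibble of the headline counts.
#'
#' @param x A `cazac_summary` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy cazac_summary
#' @export
tidy.cazac_summary <- function(x, ...) {
  dplyr::arrange(x$by_family, dplyr::desc(.data$n_activities), .data$family)
}

#' @rdname tidy.cazac_summary
#' @method glance cazac_summary
#' @export
glance.cazac_summary <- function(x, ...) {
  tibble(
    n_lines = x$n_lines,
    n_activities = x$n_activities,
    n_families = length(x$families),
    n_hydrolases = x$by_role[["hydrolase"]],
    n_phosphorylases = x$by_role[["phosphorylase"]],
    n_transglycosylases = x$by_role[["transglycosylase"]],
    n_mutases = x$by_role[["mutase"]],
    n_lyases = x$by_role[["lyase"]],
    n_oxidases = x$by_role[["oxidase"]]
  )
}

#' Plot a result summary
#'
#' Bar chart of the number of distinct activities per family, ordered by
#' decreasing count.
#'
#' @param object A `cazac_summary` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cazac_summary
#' @export
autoplot.cazac_summary <- function(object, ...) {
  df <- tidy(object)
  df$family <- factor(df$family, levels = rev(df$family))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_activities, y = .data$family)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "distinct activities", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.cazac_summary
#' @param x A `cazac_summary` object.
#' @export
plot_summary <- function(x, ...) autoplot.cazac_summary(x, ...)
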