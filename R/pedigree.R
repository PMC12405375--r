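#' Pedigrees
#'
#' A pedigree is a tibble with columns `id`, `mother`, `father`
#' (`NA` = unknown) and `generation`. It must be acyclic; on validation
#' the records are re-ordered topologically so that every known parent
#' precedes its offspring.
#'
#' @param ped a data frame with columns `id`, `mother`, `father`,
#'   `generation`.
#' @return A topologically ordered tibble of class `pedigree`.
#' @export
validate_pedigree <- function(ped) {
  req <- c("id", "mother", "father", "generation")
  if (!all(req %in% names(ped))) {
    stop("pedigree needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  ped <- tibble::as_tibble(ped)
  if (anyDuplicated(ped$id)) {
    dup <- unique(ped$id[duplicated(ped$id)])
    stop("duplicate pedigree id(s): ", paste(head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  edges <- dplyr::bind_rows(
    tibble::tibble(from = ped$mother, to = ped$id),
    tibble::tibble(from = ped$father, to = ped$id)
  ) |>
    dplyr::filter(!is.na(.data$from), .data$from %in% ped$id)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = ped$id)
  if (!igraph::is_dag(g)) {
    cyc <- igraph::feedback_arc_set(g)
    ends <- igraph::ends(g, cyc)
    stop("pedigree contains a cycle involving: ",
         paste(unique(as.vector(ends)), collapse = ", "), call. = FALSE)
  }
  ord <- names(igraph::topo_sort(g, mode = "out"))
  ped <- ped[match(ord, ped$id), ]
  class(ped) <- unique(c("pedigree", class(ped)))
  ped
}

#' Read / write a pedigree
#'
#' CSV with columns `id,mother,father,generation`; `NA` marks unknown
#' parents. Reading validates and topologically orders the records;
#' cycles and duplicate ids are errors.
#'
#' @param path file path.
#' @return `read_pedigree()` returns a `pedigree` tibble;
#'   `write_pedigree()` returns `path` invisibly.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ped <- readr::read_csv(path, col_types = readr::cols(
    id = readr::col_character(), mother = readr::col_character(),
    father = readr::col_character(), generation = readr::col_character()
  ))
  validate_pedigree(ped)
}

#' @rdname read_pedigree
#' @param ped a pedigree tibble.
#' @export
write_pedigree <- function(ped, path) {
  readr::write_csv(ped[, c("id", "mother", "father", "generation")], path,
                   na = "NA")
  invisible(path)
}
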