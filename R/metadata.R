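#' Item metadata table
#'
#' Construct the questionnaire description used throughout the pipeline: one
#' row per item with its identifier, optional wording, reverse-coding flag
#' and response range.
#'
#' @param item_id character vector of unique item identifiers (e.g. "s08").
#' @param wording optional character vector of item texts; may be empty.
#' @param reverse_coded logical vector; \code{TRUE} for items worded so that
#'   a high raw response means fewer problems. Such items are recoded by
#'   [recode_reverse()] before any statistic is computed.
#' @param response_min,response_max integer response range, default 1--4.
#' @return A data frame of class \code{"item_metadata"}.
#' @examples
#' item_metadata(c("a", "b"), reverse_coded = c(FALSE, TRUE))
#' @export
item_metadata <- function(item_id, wording = "", reverse_coded = FALSE,
                          response_min = 1L, response_max = 4L) {
  item_id <- as.character(item_id)
  if (anyDuplicated(item_id))
    stop("duplicate item_id: ",
         paste(unique(item_id[duplicated(item_id)]), collapse = ", "))
  md <- data.frame(item_id = item_id,
                   wording = rep_len(as.character(wording), length(item_id)),
                   reverse_coded = rep_len(as.logical(reverse_coded),
                                           length(item_id)),
                   response_min = rep_len(as.integer(response_min),
                                          length(item_id)),
                   response_max = rep_len(as.integer(response_max),
                                          length(item_id)),
                   stringsAsFactors = FALSE)
  if (any(md$response_min >= md$response_max))
    stop("response_min must be < response_max for every item")
  class(md) <- c("item_metadata", "data.frame")
  md
}

#' Metadata of the 69-item provisional QLQ-AA/PNH questionnaire
#'
#' Items s01--s69 on a 1--4 Likert scale. Eight items (s25, s27, s45, s46,
#' s49, s66, s67, s68) are worded positively and marked reverse-coded, so
#' that after recoding higher values always indicate more problems.
#'
#' @return A data frame of class \code{"item_metadata"} with 69 rows.
#' @export
qlq_aapnh_metadata <- function() {
  ids <- sprintf("s%02d", 1:69)
  rev <- c("s25", "s27", "s45", "s46", "s49", "s66", "s67", "s68")
  item_metadata(ids, reverse_coded = ids %in% rev)
}

#' Define a hypothesised scale
#'
#' A scale is a named set of at least two items presumed to measure a single
#' construct; internal consistency of such sets is estimated by
#' [cronbach_alpha()].
#'
#' @param name scale name.
#' @param item_ids character vector of at least two distinct item ids.
#' @param metadata optional [item_metadata()] table; when supplied, all ids
#'   must exist in it.
#' @return A list of class \code{"scale_definition"}.
#' @export
scale_definition <- function(name, item_ids, metadata = NULL) {
  item_ids <- as.character(item_ids)
  if (length(item_ids) < 2L)
    stop("scale '", name, "' needs at least 2 items")
  if (anyDuplicated(item_ids))
    stop("scale '", name, "' has duplicated item ids")
  if (!is.null(metadata)) {
    unknown <- setdiff(item_ids, metadata$item_id)
    if (length(unknown))
      stop("scale '", name, "' references unknown item(s): ",
           paste(unknown, collapse = ", "))
  }
  structure(list(name = as.character(name), item_ids = item_ids),
            class = "scale_definition")
}

#' Synthetic scale grouping for the QLQ-AA/PNH items
#'
#' The field test hypothesised eleven scales (fatigue, infections, other
#' symptoms, physical / role / emotional functioning, stigmatisation, body
#' image, social support, fear of progression, illness intrusiveness) but
#' their item memberships are not published. This function returns a fixed
#' synthetic assignment of the 69 items to those eleven scale names, chosen
#' once by content so that every item belongs to exactly one scale. It is
#' used as the default grouping of the cohort simulator and in examples; it
#' is not the instrument's published scoring.
#'
#' @return A named list of character vectors partitioning s01..s69.
#' @export
qlq_aapnh_scales <- function() {
  s <- function(i) sprintf("s%02d", i)
  list(
    fatigue                = s(c(3:8, 29)),
    physical_functioning   = s(c(9, 14:17)),
    role_functioning       = s(c(20, 23:26)),
    emotional_functioning  = s(c(35, 36, 40, 59, 63, 64, 67)),
    infections             = s(c(12, 37, 38)),
    other_symptoms         = s(c(1, 2, 11, 13, 18, 19)),
    stigmatisation         = s(c(50, 51, 52, 65)),
    body_image             = s(c(60, 66, 69)),
    social_support         = s(c(45, 46, 68)),
    fear_of_progression    = s(c(10, 53:58)),
    illness_intrusiveness  = s(c(21, 22, 27, 28, 30:34, 39, 41:44, 47:49, 61, 62))
  )
}

#' Read questionnaire metadata from a YAML file
#'
#' Expected layout: a top-level \code{items} list, each element with fields
#' \code{item_id} and optionally \code{wording}, \code{reverse_coded},
#' \code{response_min}, \code{response_max}.
#'
#' @param path path to the YAML file.
#' @return A data frame of class \code{"item_metadata"}.
#' @export
read_questionnaire <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- yaml::read_yaml(path)
  items <- raw$items
  if (is.null(items) || !length(items))
    stop("questionnaire file has no 'items' entry: ", path)
  grab <- function(it, field, default) {
    v <- it[[field]]
    if (is.null(v)) default else v
  }
  item_metadata(
    item_id = vapply(items, function(it) as.character(it$item_id), ""),
    wording = vapply(items, grab, "", field = "wording", default = ""),
    reverse_coded = vapply(items, grab, NA, field = "reverse_coded",
                           default = FALSE),
    response_min = vapply(items, grab, 0L, field = "response_min",
                          default = 1L),
    response_max = vapply(items, grab, 0L, field = "response_max",
                          default = 4L))
}

#' Read scale definitions from a YAML file
#'
#' Expected layout: a mapping of scale name to a list of item ids.
#'
#' @param path path to the YAML file.
#' @param metadata optional [item_metadata()] table for id validation.
#' @return A named list of character vectors of item ids.
#' @export
read_scales <- function(path, metadata = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw) || !length(raw) || is.null(names(raw)))
    stop("scales file must map scale names to item id lists: ", path)
  out <- lapply(names(raw), function(nm) {
    scale_definition(nm, unlist(raw[[nm]]), metadata = metadata)$item_ids
  })
  names(out) <- names(raw)
  out
}
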