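#' Describe a published source gene list
#'
#' A source list is one publication's directional differential-expression
#' call set: features reported up and features reported down.  Within-source
#' duplicates are collapsed, so a source contributes at most one vote per
#' feature per direction.
#'
#' @param up,down Character vectors of feature ids.
#' @param source_name Label for the publication or dataset.
#' @return An object of class `source_list`.
#' @export
source_list <- function(up = character(), down = character(),
                        source_name = "source") {
  up <- unique(trimws(as.character(up)))
  down <- unique(trimws(as.character(down)))
  both <- intersect(up, down)
  if (length(both))
    stop("source '", source_name, "' lists features in both directions: ",
         paste(both, collapse = ", "))
  structure(list(source_name = as.character(source_name)[1L],
                 up = up[up != ""], down = down[down != ""]),
            class = "source_list")
}

#' Build a consensus signature by minimum-support voting
#'
#' Combines several published directional gene lists into a single
#' consensus signature: a feature enters the consensus "up" set when at
#' least `min_support` sources list it as up (and symmetrically for
#' "down").  Features reaching the support threshold in both directions are
#' contradictory across the literature; they are excluded from the
#' consensus and returned in a conflict report rather than silently
#' assigned a direction.
#'
#' @param sources List of [source_list()] objects (a plain
#'   `directional_signature` is accepted too).
#' @param min_support Minimum number of supporting sources per direction,
#'   between 1 and `length(sources)`.
#' @return A [directional_signature()] whose name records the sources and
#'   threshold, with attribute `conflicts` (character vector of excluded
#'   direction-discordant features).
#' @examples
#' a <- source_list(up = c("m1", "m2"), source_name = "A")
#' b <- source_list(up = c("m2", "m3"), source_name = "B")
#' build_consensus(list(a, b), min_support = 2)  # up = {m2}
#' @export
build_consensus <- function(sources, min_support) {
  if (!is.list(sources) || !length(sources))
    stop("sources must be a nonempty list of source lists")
  if (inherits(sources, c("source_list", "directional_signature")))
    sources <- list(sources)
  min_support <- as.integer(min_support)
  if (length(min_support) != 1L || is.na(min_support) || min_support < 1L)
    stop("min_support must be a positive integer")
  if (min_support > length(sources))
    stop("min_support (", min_support, ") exceeds the number of sources (",
         length(sources), ")")
  ups <- lapply(sources, function(s) unique(s$up))
  downs <- lapply(sources, function(s) unique(s$down))
  up_support <- table(unlist(ups))
  down_support <- table(unlist(downs))
  up_hit <- names(up_support)[up_support >= min_support]
  down_hit <- names(down_support)[down_support >= min_support]
  conflicts <- sort(intersect(up_hit, down_hit))
  src_names <- vapply(sources, function(s) {
    if (!is.null(s$source_name)) s$source_name else s$name
  }, "")
  if (!length(setdiff(c(up_hit, down_hit), conflicts)))
    stop("no feature is listed consistently in one direction by at least ",
         min_support, " source(s); consensus is empty")
  sig <- directional_signature(
    up = sort(setdiff(up_hit, conflicts)),
    down = sort(setdiff(down_hit, conflicts)),
    name = sprintf("consensus(%s; min_support=%d)",
                   paste(src_names, collapse = ","), min_support))
  attr(sig, "conflicts") <- conflicts
  attr(sig, "min_support") <- min_support
  sig
}

#' Report signature coverage in an expression matrix
#'
#' Signature scoring only uses members present among the matrix features;
#' this reports, per direction, the fraction present and the missing
#' members, so a low-coverage (hence unreliable) scoring run can be
#' recognized before it happens.  An empty direction is vacuously complete
#' (fraction 1).
#'
#' @param sig A [directional_signature()].
#' @param mat Expression matrix (features x samples).
#' @return A list with `up_fraction`, `down_fraction`, `missing_up`,
#'   `missing_down`.
#' @export
signature_coverage <- function(sig, mat) {
  stopifnot(inherits(sig, "directional_signature"))
  validate_expression_matrix(mat)
  feats <- rownames(mat)
  frac <- function(members) {
    if (!length(members)) return(1)
    mean(members %in% feats)
  }
  list(up_fraction = frac(sig$up),
       down_fraction = frac(sig$down),
       missing_up = setdiff(sig$up, feats),
       missing_down = setdiff(sig$down, feats))
}
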