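# Axial-skeleton nomenclature atlas for zebrafish. The vertebral column is
# regionalized into Weberian (postcranial), abdominal (synonym: precaudal),
# transitional, caudal, and caudal-fin vertebrae. The modal wild-type column
# has 31 vertebrae; v29-v31 support the caudal fin, with v29 doubling as the
# last caudal vertebra, so the region ranges stay non-overlapping while the
# modal fin-supporting count is 3.

REGION_NAMES <- c("Weberian", "abdominal", "transitional", "caudal",
                  "caudal fin")
REGION_ALIASES <- c(precaudal = "abdominal", postcranial = "Weberian")

SKULL_BONE_LABELS <- c(
  "frontal", "parietal", "pterotic bone", "opercle", "sub-opercular",
  "interopercular", "pre-opercular", "hyomandibular", "sphenoid",
  "pterosphenoid", "orbitosphenoid", "parasphenoid", "ectopterigoid",
  "metapterigoid", "quadrate", "anguloarticular", "dentary", "maxillary",
  "pre-maxillary", "retroarticular", "supraoccipital", "basioccipital",
  "exoccipital", "epioccipital", "post-temporal", "sphenotic",
  "supra-orbital", "lateral ethmoid", "nasal", "ethmoid", "kin-ethmoid",
  "pre-ethmoid")

new_axial_atlas <- function(counts, fin_supporting = NULL, warn = TRUE) {
  counts <- as.integer(counts)
  if (length(counts) != 5L || any(counts < 0))
    stop("need 5 non-negative region counts", call. = FALSE)
  total <- sum(counts)
  if (total == 0L) stop("atlas with zero vertebrae", call. = FALSE)
  if (warn && counts[3] != 1L)
    warning("transitional region typically has exactly 1 vertebra", call. = FALSE)
  ends <- cumsum(counts)
  starts <- ends - counts + 1L
  regions <- data.frame(region = REGION_NAMES, from = starts, to = ends,
                        count = counts, stringsAsFactors = FALSE)
  regions <- regions[regions$count > 0, ]
  structure(list(regions = regions, total_vertebrae = total,
                 fin_supporting = fin_supporting,
                 skull_bone_labels = SKULL_BONE_LABELS),
            class = "axial_atlas")
}

#' Default zebrafish axial atlas
#'
#' The modal wild-type composition: 31 vertebrae with Weberian v1-v4,
#' abdominal v5-v14, transitional v15, caudal v16-v29, and caudal-fin
#' vertebrae v30-v31 completing the total. The fin-supporting range is
#' v29-v31 (modal count 3): the most posterior caudal vertebra is modified
#' to support the fin as well, which is why the printed modal composition
#' (4 Weberian + 10 precaudal + 14 caudal + 3 caudal fin = 31) overlaps the
#' caudal range at v29.
#'
#' @return An `axial_atlas` with fields `regions` (data.frame region/from/
#'   to/count), `total_vertebrae`, `fin_supporting` (index range),
#'   `skull_bone_labels` (32 named skull bones visible on uCT).
#' @export
default_atlas <- function() {
  new_axial_atlas(c(4L, 10L, 1L, 14L, 2L), fin_supporting = c(29L, 31L))
}

#' @export
print.axial_atlas <- function(x, ...) {
  cat(sprintf("<axial_atlas> %d vertebrae\n", x$total_vertebrae))
  for (i in seq_len(nrow(x$regions)))
    cat(sprintf("  %-12s v%d-v%d (%d)\n", x$regions$region[i],
                x$regions$from[i], x$regions$to[i], x$regions$count[i]))
  if (!is.null(x$fin_supporting))
    cat(sprintf("  fin-supporting: v%d-v%d\n", x$fin_supporting[1],
                x$fin_supporting[2]))
  invisible(x)
}

#' Region of a vertebra
#'
#' @param atlas an `axial_atlas`.
#' @param v 1-based vertebra index.
#' @return Region name (canonical; `"abdominal"` rather than the
#'   `"precaudal"` synonym).
#' @export
region_of_vertebra <- function(atlas, v) {
  if (!inherits(atlas, "axial_atlas")) stop("expected an axial_atlas", call. = FALSE)
  v <- as.integer(v)
  if (length(v) != 1L || is.na(v) || v < 1L || v > atlas$total_vertebrae)
    stop(sprintf("vertebra index out of range 1..%d", atlas$total_vertebrae),
         call. = FALSE)
  hit <- atlas$regions$from <= v & atlas$regions$to >= v
  atlas$regions$region[which(hit)[1]]
}

#' Does a vertebra support the caudal fin?
#'
#' @param atlas an `axial_atlas`.
#' @param v 1-based vertebra index.
#' @return Logical.
#' @export
supports_caudal_fin <- function(atlas, v) {
  if (is.null(atlas$fin_supporting)) return(FALSE)
  v >= atlas$fin_supporting[1] & v <= atlas$fin_supporting[2]
}

#' Build a custom atlas from per-region counts
#'
#' Vertebral counts vary between wild-type individuals; this builds
#' contiguous ranges in the canonical order Weberian, abdominal,
#' transitional, caudal, caudal fin. A transitional count other than 1 is
#' allowed with a warning. `"precaudal"`/`"postcranial"` are accepted as
#' aliases in named input.
#'
#' @param counts numeric vector of 5 counts, optionally named with region
#'   names or aliases.
#' @return An `axial_atlas`.
#' @export
build_custom_atlas <- function(counts) {
  if (!is.null(names(counts))) {
    nm <- names(counts)
    canon <- ifelse(nm %in% names(REGION_ALIASES), REGION_ALIASES[nm], nm)
    if (!setequal(canon, REGION_NAMES))
      stop("counts must name all five regions", call. = FALSE)
    counts <- counts[match(REGION_NAMES, canon)]
  }
  atlas <- new_axial_atlas(counts)
  total <- atlas$total_vertebrae
  fin_count <- atlas$regions$count[atlas$regions$region == "caudal fin"]
  if (length(fin_count) && fin_count > 0)
    atlas$fin_supporting <- c(total - as.integer(fin_count), total)
  atlas
}

#' Atlas as JSON
#'
#' @param atlas an `axial_atlas`.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_atlas_json <- function(atlas, path) {
  jsonlite::write_json(
    list(total_vertebrae = atlas$total_vertebrae,
         regions = atlas$regions,
         fin_supporting = atlas$fin_supporting,
         skull_bone_labels = atlas$skull_bone_labels),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
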