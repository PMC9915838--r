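# Pedigree handling -------------------------------------------------------

#' Read a 6-column PED pedigree file
#'
#' Standard whitespace-delimited PED: family, individual, father, mother,
#' sex (1 = male, 2 = female, 0 = unknown), affected status (2 = affected,
#' 1 = unaffected, 0 = unknown). `0` parent ids denote an absent parent.
#' Parent ids must resolve within the family; cyclic parentage is fatal.
#'
#' @param path Path to a PED file.
#' @return A data frame of class `pedigree` with columns `family`, `id`,
#'   `father`, `mother` (both `NA` when absent), `sex` (`"M"`/`"F"`/`NA`)
#'   and `affected` (logical, `NA` when unknown).
#' @export
read_pedigree <- function(path) {
  raw <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character",
                    col.names = c("family", "id", "father", "mother",
                                  "sex", "affected"))
  as_pedigree(raw)
}

#' Build a pedigree from a data frame
#'
#' @param df Data frame with PED-convention columns `family`, `id`,
#'   `father`, `mother`, `sex`, `affected` (codes as in [read_pedigree()],
#'   or already-decoded `"M"`/`"F"` and logical affected values).
#' @return A `pedigree` object.
#' @export
as_pedigree <- function(df) {
  ped <- data.frame(
    family = as.character(df$family), id = as.character(df$id),
    father = ifelse(df$father %in% c("0", "", NA), NA_character_,
                    as.character(df$father)),
    mother = ifelse(df$mother %in% c("0", "", NA), NA_character_,
                    as.character(df$mother)),
    sex = decode_sex(df$sex),
    affected = decode_affected(df$affected),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(ped$id)) stop("duplicate individual ids in pedigree")
  for (i in seq_len(nrow(ped))) {
    for (p in c("father", "mother")) {
      pid <- ped[[p]][i]
      if (!is.na(pid) && !pid %in% ped$id[ped$family == ped$family[i]])
        stop("parent id '", pid, "' of individual '", ped$id[i],
             "' does not resolve within family ", ped$family[i])
    }
  }
  check_acyclic(ped)
  structure(ped, class = c("pedigree", "data.frame"))
}

decode_sex <- function(x) {
  x <- as.character(x)
  out <- ifelse(x %in% c("1", "M", "m"), "M",
                ifelse(x %in% c("2", "F", "f"), "F", NA_character_))
  out
}

decode_affected <- function(x) {
  if (is.logical(x)) return(x)
  x <- as.character(x)
  ifelse(x %in% c("2", "TRUE"), TRUE,
         ifelse(x %in% c("1", "FALSE"), FALSE, NA))
}

check_acyclic <- function(ped) {
  parents <- function(id) {
    r <- ped[ped$id == id, ]
    stats::na.omit(c(r$father, r$mother))
  }
  for (start in ped$id) {
    frontier <- parents(start)
    seen <- start
    while (length(frontier)) {
      if (any(frontier %in% seen))
        stop("cyclic parentage involving individual '", start, "'")
      seen <- c(seen, frontier)
      frontier <- unlist(lapply(frontier, parents))
    }
  }
  invisible(ped)
}

#' Enumerate analysis trios from a pedigree
#'
#' Each affected individual defines one analysis unit comprising the
#' individual and whichever parents are present. Quad families (two
#' affected children with shared parents) therefore decompose into two
#' trios with the parents duplicated, mirroring how such families are
#' sequenced clinically.
#'
#' @param ped A [read_pedigree()] object.
#' @return Data frame with one row per analysis trio: `family`, `proband`,
#'   `father`, `mother` (NA when absent) and `sex`.
#' @export
analysis_trios <- function(ped) {
  aff <- ped[!is.na(ped$affected) & ped$affected, , drop = FALSE]
  if (nrow(aff) == 0) stop("pedigree contains no affected individual")
  data.frame(family = aff$family, proband = aff$id, father = aff$father,
             mother = aff$mother, sex = aff$sex, stringsAsFactors = FALSE)
}
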