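#' Read a 6-column PED pedigree file
#'
#' Parses a standard whitespace-separated PED file (family id, individual id,
#' father id, mother id, sex, affection status) and resolves the family roles
#' the segregation analysis needs: exactly one father, one mother, and at
#' least one affected child listing both as parents.
#'
#' Sex is coded 1 = male, 2 = female, anything else = unknown; affection is
#' coded 2 = affected, 1 = unaffected, anything else (0, -9) = unknown.
#'
#' @param path Path to a PED file.
#' @return An object of class `pedigree`: a list with `members` (a data.frame
#'   in file order with columns `family_id`, `individual_id`, `father_id`,
#'   `mother_id`, `sex`, `affected`) and `roles` (list with `father`,
#'   `mother`, `affected_children`).
#' @examples
#' ped_file <- tempfile(fileext = ".ped")
#' writeLines(c("FAM1 F1 0 0 1 1", "FAM1 M1 0 0 2 1",
#'              "FAM1 C1 F1 M1 2 2", "FAM1 C2 F1 M1 1 2"), ped_file)
#' ped <- read_pedigree(ped_file)
#' ped$roles$affected_children
#' @export
read_pedigree <- function(path) {
  stopifnot(file.exists(path))
  raw <- utils::read.table(path, header = FALSE, colClasses = "character",
                           comment.char = "#", blank.lines.skip = TRUE)
  if (ncol(raw) < 6L)
    stop("PED file must have 6 whitespace-separated columns, got ", ncol(raw))
  members <- data.frame(
    family_id     = raw[[1L]],
    individual_id = raw[[2L]],
    father_id     = raw[[3L]],
    mother_id     = raw[[4L]],
    sex      = c("male", "female")[match(raw[[5L]], c("1", "2"))],
    affected = c("unaffected", "affected")[match(raw[[6L]], c("1", "2"))],
    stringsAsFactors = FALSE
  )
  members$sex[is.na(members$sex)] <- "unknown"
  members$affected[is.na(members$affected)] <- "unknown"
  new_pedigree(members)
}

# Validates the member table and resolves roles; shared by the reader and
# the simulator (which builds pedigrees in code).
new_pedigree <- function(members) {
  if (anyDuplicated(paste(members$family_id, members$individual_id)))
    stop("duplicate individual_id within family")
  ids <- members$individual_id
  for (col in c("father_id", "mother_id")) {
    ref <- members[[col]]
    bad <- ref != "0" & !(ref %in% ids)
    if (any(bad))
      stop("structural error: ", col, " '", ref[bad][1L],
           "' not present in pedigree file")
  }
  kids <- members$affected == "affected" &
    members$father_id != "0" & members$mother_id != "0"
  if (!any(kids))
    stop("ambiguity error: no affected child with both parents in file")
  fathers <- unique(members$father_id[kids])
  mothers <- unique(members$mother_id[kids])
  if (length(fathers) != 1L || length(mothers) != 1L)
    stop("ambiguity error: >1 candidate father/mother for the affected children")
  structure(
    list(members = members,
         roles = list(father = fathers, mother = mothers,
                      affected_children = members$individual_id[kids])),
    class = "pedigree"
  )
}

#' Write a pedigree back to PED format
#'
#' Inverse of [read_pedigree()]; round-trips losslessly for known sex and
#' affection codes (unknowns are written as 0).
#'
#' @param pedigree A `pedigree` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(pedigree, path) {
  stopifnot(inherits(pedigree, "pedigree"))
  m <- pedigree$members
  sex <- match(m$sex, c("male", "female"))
  aff <- match(m$affected, c("unaffected", "affected"))
  sex[is.na(sex)] <- 0L
  aff[is.na(aff)] <- 0L
  out <- data.frame(m$family_id, m$individual_id, m$father_id, m$mother_id,
                    sex, aff)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree:", nrow(x$members), "members; father", x$roles$father,
      "; mother", x$roles$mother, ";", length(x$roles$affected_children),
      "affected child(ren)\n")
  invisible(x)
}
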