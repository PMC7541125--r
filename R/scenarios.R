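#' Closest eligible facility per fokontany
#'
#' Argmin of the fokontany-level mean travel time over eligible
#' facilities. Facilities that support no volunteers are not eligible as
#' reassignment destinations. Ties break deterministically by facility id
#' (lexicographic).
#'
#' @param tt travel-time matrix from [travel_time_matrix()] (rows =
#'   fokontany, columns = facility ids, minutes).
#' @param eligible character vector of eligible facility ids (default all
#'   columns).
#' @return data.frame: `fokontany_id`, `closest_id`, `closest_minutes`.
#' @export
closest_facility <- function(tt, eligible = colnames(tt)) {
  eligible <- intersect(colnames(tt), eligible)
  if (!length(eligible)) stop("no eligible facility")
  sub <- tt[, sort(eligible), drop = FALSE]
  idx <- apply(sub, 1, which.min)   # first minimum: lexicographic tie-break
  data.frame(
    fokontany_id = rownames(tt),
    closest_id = colnames(sub)[idx],
    closest_minutes = sub[cbind(seq_len(nrow(sub)), idx)],
    stringsAsFactors = FALSE
  )
}

#' Assigned-versus-closest reassignment scenario
#'
#' For one facility kind (CSB or PA), pairs each fokontany's travel time
#' to its currently assigned facility with the time to its closest
#' eligible facility. Fokontany without an assigned facility of this kind
#' (e.g., no supply point in the commune) are excluded with a reason and
#' carry no times.
#'
#' @param roster data.frame with `fokontany_id` and the assignment column.
#' @param tt travel-time matrix for facilities of this kind.
#' @param kind `"CSB"` or `"PA"`.
#' @param eligible eligible facility ids (default: ids that appear as an
#'   assignment in the roster, i.e. facilities that support at least one
#'   volunteer).
#' @return data.frame of scenario records: `fokontany_id`, `facility_kind`,
#'   `assigned_id`, `assigned_minutes`, `closest_id`, `closest_minutes`,
#'   `misassigned`, `excluded`, `exclusion_reason`.
#' @export
scenario_table <- function(roster, tt, kind = c("CSB", "PA"),
                           eligible = NULL) {
  kind <- match.arg(kind)
  col <- if (kind == "CSB") "assigned_csb_id" else "assigned_pa_id"
  stopifnot(col %in% names(roster), all(roster$fokontany_id %in% rownames(tt)))
  assigned <- roster[[col]][match(rownames(tt), roster$fokontany_id)]
  if (is.null(eligible)) eligible <- unique(stats::na.omit(assigned))
  bad <- setdiff(stats::na.omit(assigned), colnames(tt))
  if (length(bad))
    stop("assigned facility id(s) missing from travel-time matrix: ",
         paste(bad, collapse = ", "))
  cl <- closest_facility(tt, eligible)
  out <- data.frame(
    fokontany_id = rownames(tt),
    facility_kind = kind,
    assigned_id = assigned,
    assigned_minutes = ifelse(is.na(assigned), NA_real_,
                              tt[cbind(seq_len(nrow(tt)),
                                       match(assigned, colnames(tt)))]),
    closest_id = cl$closest_id,
    closest_minutes = cl$closest_minutes,
    stringsAsFactors = FALSE
  )
  out$misassigned <- !is.na(out$assigned_id) & out$assigned_id != out$closest_id
  out$excluded <- is.na(out$assigned_id)
  out$exclusion_reason <- ifelse(out$excluded,
    if (kind == "PA") "no PA in commune" else "no assigned CSB", "")
  out$closest_id[out$excluded] <- NA_character_
  out$closest_minutes[out$excluded] <- NA_real_
  out
}

#' Travel-time bins
#'
#' The report's three accessibility bands: within 2 hours (inclusive),
#' over 2 and up to 4 hours, and over 4 hours one-way on foot.
#'
#' @param minutes numeric vector of travel times (minutes); `NA`s
#'   (excluded fokontany) are dropped.
#' @return named proportions over `c("<=2h", "2-4h", ">4h")`, summing to 1;
#'   attribute `n` gives the count used.
#' @export
bin_travel_times <- function(minutes) {
  m <- minutes[!is.na(minutes)]
  b <- cut(m, breaks = c(-Inf, 120, 240, Inf),
           labels = c("<=2h", "2-4h", ">4h"), right = TRUE)
  p <- as.numeric(table(b)) / length(m)
  names(p) <- levels(b)
  attr(p, "n") <- length(m)
  p
}

#' District-level travel-time summary
#'
#' Min, max, mean and median one-way travel time in hours, per district
#' and pooled, for the assigned and the closest facility. Hours are
#' reported to 2 decimal places.
#'
#' @param scenario data.frame from [scenario_table()].
#' @param district named character vector: fokontany_id -> district id.
#' @return data.frame with one row per (district x scenario) plus pooled
#'   rows.
#' @export
district_summary <- function(scenario, district) {
  s <- scenario[!scenario$excluded, ]
  dis <- as.character(district[s$fokontany_id])
  one <- function(mins, dname, which) {
    h <- mins / 60
    data.frame(district = dname, scenario = which,
               n = length(h),
               min_h = round(min(h), 2), max_h = round(max(h), 2),
               mean_h = round(mean(h), 2), median_h = round(stats::median(h), 2),
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (d in sort(unique(dis))) {
    sel <- dis == d
    rows[[length(rows) + 1]] <- one(s$assigned_minutes[sel], d, "assigned")
    rows[[length(rows) + 1]] <- one(s$closest_minutes[sel], d, "closest")
  }
  rows[[length(rows) + 1]] <- one(s$assigned_minutes, "all", "assigned")
  rows[[length(rows) + 1]] <- one(s$closest_minutes, "all", "closest")
  do.call(rbind, rows)
}
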