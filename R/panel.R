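# Assay registry: the SRM panel for the NAD+ metabolome.
#
# The built-in panel models the published assay: 19 quantifiable metabolites
# (16 resolved in an alkaline separation, plus Nam, NA and NR in an acidic
# one) and NADPH, whose channel is monitored but never reported because
# on-source oxidation makes it unreliable. Each row carries the SRM
# transition, collision energy, cone voltage, expected retention time and
# separation membership. Heavy internal-standard channels come from two sets:
# a uniformly 13C-glucose-grown yeast extract (one ribose = +5 Da, two
# riboses = +10 Da; Nam and NA carry no carbohydrate and are not labelled)
# and 18O-labelled Nam and NR (+2 Da) for the acidic separation.

RUN_LENGTH <- c(alkaline = 32.2, acidic = 23.4)

#' @rdname load_registry
#' @export
run_length <- function(separation) {
  separation <- match.arg(separation, names(RUN_LENGTH), several.ok = TRUE)
  unname(RUN_LENGTH[separation])
}

builtin_metabolites <- function() {
  df <- utils::read.table(header = TRUE, stringsAsFactors = FALSE,
                          na.strings = "", text = "
name      precursor_mz fragment_mz collision_energy cone_voltage rt_min separation quantifiable
Nam       123 96  16 32  9.82 acidic   TRUE
NA        124 53  26 32  8.35 acidic   TRUE
Cytidine  244 112 18 18 11.14 alkaline TRUE
Uridine   245 113 16 18 11.50 alkaline TRUE
NR        255 123 12 14  8.98 acidic   TRUE
NAR       256 124 13 14 10.33 alkaline TRUE
Inosine   269 137 12 12 12.88 alkaline TRUE
CMP       324 112 22 16  2.97 alkaline TRUE
UMP       325 97  12 20  4.11 alkaline TRUE
NMN       335 123 12 16  8.92 alkaline TRUE
NAMN      336 124 12 18  4.20 alkaline TRUE
IMP       349 137 22 14  9.65 alkaline TRUE
ADP       428 136 26 30 10.43 alkaline TRUE
ATP       508 410 16 30 10.51 alkaline TRUE
ADPr      560 348 16 26 11.08 alkaline TRUE
NAD       664 428 26 26 13.64 alkaline TRUE
NAAD      665 428 24 24 11.89 alkaline TRUE
NADH      666 649 20 26 12.98 alkaline TRUE
NADP      744 604 18 26 12.01 alkaline TRUE
NADPH     745 729 48 28 12.50 alkaline FALSE
")
  df$notes <- ""
  df$notes[df$name == "NADPH"] <-
    "monitored but not reported: cannot be reliably quantified (oxidation); assumed RT"
  df$notes[df$name == "NADP"] <-
    "may include oxidized NADPH; interpret with care"
  df$notes[df$name == "Nam"] <-
    "strikingly membrane permeable; losses to supernatants possible"
  df
}

# Heavy internal-standard channel definitions. mass_offset applies to the
# precursor; fragment_offset is stored explicitly per metabolite (default:
# the full offset when the fragment retains every labelled ribose, reduced
# where the monitored fragment sheds a ribose, e.g. ADP 428>136 whose 136
# fragment is the adenine base).
builtin_heavy <- function() {
  one_ribose <- c("Cytidine", "Uridine", "NR", "NAR", "Inosine", "CMP", "UMP",
                  "NMN", "NAMN", "IMP", "ADP", "ATP")
  two_ribose <- c("ADPr", "NAD", "NAAD", "NADH", "NADP", "NADPH")
  # fragments that shed all labelled riboses (base/pyridine-only fragments)
  base_fragment <- c(Nam = 2, ADP = 0, NMN = 0, NAMN = 0, IMP = 0, Inosine = 0,
                     CMP = 0, NR = 2)
  h <- rbind(
    data.frame(metabolite = one_ribose, standard_set = "C13_extract",
               mass_offset = 5L, stringsAsFactors = FALSE),
    data.frame(metabolite = two_ribose, standard_set = "C13_extract",
               mass_offset = 10L, stringsAsFactors = FALSE),
    data.frame(metabolite = c("Nam", "NR"), standard_set = "O18_vitamins",
               mass_offset = 2L, stringsAsFactors = FALSE)
  )
  h$fragment_offset <- h$mass_offset
  keep_base <- h$metabolite %in% names(base_fragment) &
    !(h$metabolite %in% c("Nam", "NR") & h$standard_set == "C13_extract")
  h$fragment_offset[keep_base] <- base_fragment[h$metabolite[keep_base]]
  h
}

# Default crosstalk map. Fragmentation signal and bleed signal both appear at
# the SOURCE metabolite's retention time in the target channel.
builtin_crosstalk <- function() {
  utils::read.table(header = TRUE, stringsAsFactors = FALSE,
                    na.strings = "", text = "
source   target  mechanism               fraction
NR       Nam     on_source_fragmentation 0.10
NMN      Nam     on_source_fragmentation 0.10
NAR      NA      on_source_fragmentation 0.10
NAMN     NA      on_source_fragmentation 0.10
Cytidine Uridine isotopologue_bleed      0.05
Nam      NA      isotopologue_bleed      0.05
")
}

#' Load and validate an SRM panel
#'
#' `load_registry()` returns the validated assay panel: metabolite SRM
#' specifications, heavy internal-standard channel definitions and the
#' crosstalk map. With no arguments the built-in NAD+ metabolome panel is
#' returned; CSV paths may be supplied to override the metabolite table
#' (`name,precursor_mz,fragment_mz,collision_energy,cone_voltage,rt_min,separation,quantifiable`)
#' and/or the crosstalk map (`source,target,mechanism,fraction`).
#'
#' Validation enforces: unique names; `precursor_mz > fragment_mz > 0` for
#' every quantifiable metabolite; retention times inside the separation's run
#' length (alkaline 32.2 min, acidic 23.4 min); exactly Nam, NA and NR in the
#' acidic separation; no quantifiable AMP (AMP cannot be distinguished from
#' on-source fragments of ATP/ADP); crosstalk endpoints present in the panel.
#'
#' @param panel_file optional CSV path for the metabolite table.
#' @param crosstalk_file optional CSV path for the crosstalk map.
#' @return an object of class `nad_panel`: a list with data.frame components
#'   `metabolites`, `heavy` and `crosstalk`.
#' @examples
#' panel <- load_registry()
#' subset(panel$metabolites, name == "NAD")
#' @export
load_registry <- function(panel_file = NULL, crosstalk_file = NULL) {
  mets <- if (is.null(panel_file)) builtin_metabolites() else {
    df <- utils::read.csv(panel_file, stringsAsFactors = FALSE, na.strings = "")
    if (nrow(df) == 0L) stop("panel file is empty: no metabolites defined")
    if (!"notes" %in% names(df)) df$notes <- ""
    df
  }
  xt <- if (is.null(crosstalk_file)) builtin_crosstalk() else
    utils::read.csv(crosstalk_file, stringsAsFactors = FALSE, na.strings = "")
  panel <- structure(
    list(metabolites = mets, heavy = builtin_heavy(), crosstalk = xt),
    class = "nad_panel")
  # drop heavy rows whose metabolite is not in a user-supplied panel
  panel$heavy <- panel$heavy[panel$heavy$metabolite %in% mets$name, ]
  validate_panel(panel)
  panel
}

validate_panel <- function(panel) {
  m <- panel$metabolites
  req <- c("name", "precursor_mz", "fragment_mz", "collision_energy",
           "cone_voltage", "rt_min", "separation", "quantifiable")
  miss <- setdiff(req, names(m))
  if (length(miss))
    stop("panel is missing columns: ", paste(miss, collapse = ", "))
  dup <- m$name[duplicated(m$name)]
  if (length(dup))
    stop("duplicate metabolite name(s): ", paste(unique(dup), collapse = ", "))
  if (!all(m$separation %in% names(RUN_LENGTH)))
    stop("unknown separation in rows: ",
         paste(m$name[!m$separation %in% names(RUN_LENGTH)], collapse = ", "))
  q <- m[m$quantifiable, ]
  bad <- q$name[!(q$precursor_mz > q$fragment_mz & q$fragment_mz > 0)]
  if (length(bad))
    stop("invalid transition (need precursor > fragment > 0) for: ",
         paste(bad, collapse = ", "))
  bad <- q$name[is.na(q$rt_min)]
  if (length(bad))
    stop("missing retention time for quantifiable metabolite(s): ",
         paste(bad, collapse = ", "))
  out <- m$name[m$rt_min <= 0 | m$rt_min > RUN_LENGTH[m$separation]]
  if (length(out))
    stop("retention time outside the run length for: ",
         paste(out, collapse = ", "))
  if ("AMP" %in% q$name)
    stop("AMP cannot be quantified by this assay (on-source ATP/ADP ",
         "fragments co-detect); remove it or set quantifiable = FALSE")
  xt <- panel$crosstalk
  bad <- unique(c(xt$source[!xt$source %in% m$name],
                  xt$target[!xt$target %in% m$name]))
  if (length(bad))
    stop("crosstalk rule references unknown metabolite(s): ",
         paste(bad, collapse = ", "))
  if (!all(xt$mechanism %in% c("on_source_fragmentation", "isotopologue_bleed")))
    stop("unknown crosstalk mechanism")
  if (any(xt$fraction < 0 | xt$fraction >= 1))
    stop("crosstalk fractions must lie in [0, 1)")
  invisible(panel)
}

#' @export
print.nad_panel <- function(x, ...) {
  m <- x$metabolites
  cat("SRM panel:", nrow(m), "metabolites (",
      sum(m$separation == "alkaline"), "alkaline /",
      sum(m$separation == "acidic"), "acidic ),",
      sum(m$quantifiable), "quantifiable\n")
  cat("Heavy channels:", nrow(x$heavy), " Crosstalk rules:", nrow(x$crosstalk), "\n")
  invisible(x)
}

#' Heavy-channel SRM transition
#'
#' Shifts a metabolite's light transition by its internal-standard mass
#' offsets: +5 Da per labelled ribose in the 13C yeast-extract set (+10 Da
#' for dinucleotides), +2 Da per 18O in the labelled-vitamin set. The
#' fragment offset is stored per metabolite because some monitored fragments
#' shed the labelled ribose.
#'
#' @param panel an `nad_panel`.
#' @param metabolite metabolite name.
#' @param standard_set `"C13_extract"` or `"O18_vitamins"`.
#' @return named numeric vector `c(precursor_mz, fragment_mz)`.
#' @examples
#' heavy_transition(load_registry(), "NAD", "C13_extract")  # 674 > 438
#' @export
heavy_transition <- function(panel, metabolite,
                             standard_set = c("C13_extract", "O18_vitamins")) {
  standard_set <- match.arg(standard_set)
  m <- panel$metabolites[panel$metabolites$name == metabolite, ]
  if (nrow(m) == 0L) stop("unknown metabolite: ", metabolite)
  h <- panel$heavy[panel$heavy$metabolite == metabolite &
                     panel$heavy$standard_set == standard_set, ]
  if (nrow(h) == 0L)
    stop("no ", standard_set, " heavy channel for ", metabolite,
         if (metabolite %in% c("Nam", "NA") && standard_set == "C13_extract")
           " (no carbohydrate group, so it is not labelled by heavy glucose)"
         else "")
  c(precursor_mz = m$precursor_mz + h$mass_offset,
    fragment_mz = m$fragment_mz + h$fragment_offset)
}

#' Crosstalk feeders of a channel
#'
#' Every retention time at which crosstalk can deposit signal into a
#' metabolite's channel, with a human-readable mechanism note. Direct rules
#' targeting the metabolite are included (fragmentation feeds both light and
#' heavy channels, bleed only light); because bleed copies the source
#' channel's whole content, fragmentation sources of a bleed source are
#' included transitively (e.g. NR feeds the NA channel via the on-source Nam
#' fragment's isotope bleed).
#'
#' @param panel an `nad_panel`.
#' @param metabolite channel metabolite name.
#' @param isotope `"light"` or `"heavy"`.
#' @return data.frame `source`, `rt`, `note` (zero rows for a clean channel).
#' @export
crosstalk_feeders <- function(panel, metabolite, isotope = "light") {
  xt <- panel$crosstalk
  rt_of <- stats::setNames(panel$metabolites$rt_min, panel$metabolites$name)
  mech_label <- c(on_source_fragmentation = "on-source fragmentation of",
                  isotopologue_bleed = "isotopologue bleed from")
  direct <- xt[xt$target == metabolite &
                 (isotope == "light" |
                    xt$mechanism == "on_source_fragmentation"), , drop = FALSE]
  out <- data.frame(source = direct$source,
                    rt = unname(rt_of[direct$source]),
                    note = paste(mech_label[direct$mechanism], direct$source),
                    stringsAsFactors = FALSE)
  if (isotope == "light")
    for (s in direct$source[direct$mechanism == "isotopologue_bleed"]) {
      up <- xt[xt$target == s & xt$mechanism == "on_source_fragmentation", ,
               drop = FALSE]
      if (nrow(up))
        out <- rbind(out, data.frame(
          source = up$source, rt = unname(rt_of[up$source]),
          note = paste0("isotopologue bleed from ", s,
                        " of on-source fragment of ", up$source),
          stringsAsFactors = FALSE))
    }
  out[!duplicated(out), , drop = FALSE]
}

#' Serialize / restore a panel
#'
#' Writes the three panel tables as CSV into `dir` and reads them back.
#' Round-trips bit-identically.
#'
#' @param panel an `nad_panel`.
#' @param dir directory to write into (created if needed).
#' @return `write_panel` returns `dir` invisibly; `read_panel` a `nad_panel`.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(panel$metabolites, file.path(dir, "panel.csv"), row.names = FALSE)
  utils::write.csv(panel$heavy, file.path(dir, "heavy.csv"), row.names = FALSE)
  utils::write.csv(panel$crosstalk, file.path(dir, "crosstalk.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_panel
#' @export
read_panel <- function(dir) {
  panel <- structure(list(
    metabolites = utils::read.csv(file.path(dir, "panel.csv"),
                                  stringsAsFactors = FALSE),
    heavy = utils::read.csv(file.path(dir, "heavy.csv"), stringsAsFactors = FALSE),
    crosstalk = utils::read.csv(file.path(dir, "crosstalk.csv"),
                                stringsAsFactors = FALSE)),
    class = "nad_panel")
  # read.csv turns the reserved name NA into a missing value
  for (comp in c("metabolites", "heavy", "crosstalk"))
    for (col in c("name", "metabolite", "source", "target"))
      if (col %in% names(panel[[comp]]))
        panel[[comp]][[col]][is.na(panel[[comp]][[col]])] <- "NA"
  panel$metabolites$notes[is.na(panel$metabolites$notes)] <- ""
  validate_panel(panel)
  panel
}
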