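# Attribute-expanded Markov state space and the four treatment strategies.
#
# A model state is a clinical state (NPDR, PDR, DME, SVL, DEAD) expanded by
# the attributes that make the dynamics Markovian:
#   * line        — which PDR therapy line applies next (first / second)
#   * last        — the therapy that induced the current remission (governs
#                   PDR recurrence from NPDR; carried through NPDR-origin DME)
#   * ever_prp    — whether PRP was ever administered (permanent peripheral
#                   visual-field-defect disutility)
#   * dme_origin  — which state the DME arose from (successful treatment
#                   returns the patient there)
#   * svl_tenure  — years spent in SVL (tunnel states 1..5, 5+), governing
#                   the injection-continuation probability

#' The four treatment strategies
#'
#' @return Character vector of canonical strategy names.
#' @export
pdr_strategies <- function() {
  c("prp-only", "antivegf-only", "prp-first", "antivegf-first")
}

#' Build a strategy specification
#'
#' A strategy fixes the first-line and (for two-line strategies) second-line
#' therapy for the PDR state. Single-therapy strategies never switch lines;
#' two-line strategies switch after a treated-and-failed first-line cycle.
#'
#' @param name One of `"prp-only"`, `"antivegf-only"`, `"prp-first"`,
#'   `"antivegf-first"` (underscores accepted).
#' @return A list of class `pdr_strategy` with fields `name`, `first`,
#'   `second`, `two_line`.
#' @export
strategy_spec <- function(name) {
  if (inherits(name, "pdr_strategy")) return(name)
  key <- gsub("_", "-", tolower(name))
  spec <- switch(key,
    "prp-only"       = list(first = "PRP", second = "PRP"),
    "antivegf-only"  = list(first = "antiVEGF", second = "antiVEGF"),
    "prp-first"      = list(first = "PRP", second = "antiVEGF"),
    "antivegf-first" = list(first = "antiVEGF", second = "PRP"),
    stop("unknown strategy: ", name, " (expected one of ",
         paste(pdr_strategies(), collapse = ", "), ")", call. = FALSE)
  )
  structure(c(list(name = key), spec,
              list(two_line = spec$first != spec$second)),
            class = "pdr_strategy")
}

# --- state constructors and labels ---------------------------------------

svl_tenures <- c("1", "2", "3", "4", "5", "5plus")

st_pdr <- function(line, ever)
  list(clinical = "PDR", line = line, last = NA_character_, ever_prp = ever,
       dme_origin = NA_character_, svl_tenure = NA_character_)
st_npdr <- function(line, last, ever)
  list(clinical = "NPDR", line = line, last = last, ever_prp = ever,
       dme_origin = NA_character_, svl_tenure = NA_character_)
st_dme <- function(origin, line, last, ever)
  list(clinical = "DME", line = line, last = last, ever_prp = ever,
       dme_origin = origin, svl_tenure = NA_character_)
st_svl <- function(tenure, ever)
  list(clinical = "SVL", line = NA_character_, last = NA_character_,
       ever_prp = ever, dme_origin = NA_character_, svl_tenure = tenure)
st_dead <- function()
  list(clinical = "DEAD", line = NA_character_, last = NA_character_,
       ever_prp = FALSE, dme_origin = NA_character_,
       svl_tenure = NA_character_)

state_label <- function(s) {
  switch(s$clinical,
    PDR  = paste0("PDR|", s$line, "|", if (s$ever_prp) "pvfd" else "novfd"),
    NPDR = paste0("NPDR|", s$line, "|", s$last, "|",
                  if (s$ever_prp) "pvfd" else "novfd"),
    DME  = paste0("DME:", s$dme_origin, "|", s$line, "|",
                  if (is.na(s$last)) "." else s$last, "|",
                  if (s$ever_prp) "pvfd" else "novfd"),
    SVL  = paste0("SVL|t", s$svl_tenure, "|",
                  if (s$ever_prp) "pvfd" else "novfd"),
    DEAD = "DEAD")
}

next_tenure <- function(t) {
  i <- match(t, svl_tenures)
  svl_tenures[min(i + 1, length(svl_tenures))]
}

#' PDR treatment success and recurrence probabilities
#'
#' PRP uses the directly observed success and recurrence rates; anti-VEGF
#' applies the effectiveness and recurrence relative risks to the PRP
#' rates, capped at 1.
#'
#' @param therapy `"PRP"` or `"antiVEGF"`.
#' @param params A `pdr_params` tibble or named value list.
#' @return Named numeric vector `c(success = , recurrence = )`.
#' @examples
#' pdr_treatment_probs("antiVEGF", default_parameters())
#' # success 0.2008 * 1.75 = 0.3514, recurrence 0.0169 * 1.15 = 0.019435
#' @export
pdr_treatment_probs <- function(therapy, params) {
  plist <- if (is.list(params) && is.null(params$name)) params
           else param_values(params)
  s <- pv(plist, "p_PRP_success")
  r <- pv(plist, "p_recur_post_PRP")
  if (therapy == "antiVEGF") {
    s <- min(1, s * pv(plist, "rr_antiVEGF_vs_PRP_effect"))
    r <- min(1, r * pv(plist, "rr_recur_antiVEGF_vs_PRP"))
  } else if (therapy != "PRP") {
    stop("unknown therapy: ", therapy, call. = FALSE)
  }
  c(success = s, recurrence = r)
}

# Probability that >= 1 of `n` injections causes endophthalmitis with
# failed treatment, i.e. an injection-related transition to SVL.
endo_svl_prob <- function(plist, n_inj) {
  pe <- pv(plist, "p_endoph_per_injection") *
    (1 - pv(plist, "p_endoph_treat_success"))
  1 - (1 - pe)^n_inj
}

# Successor distribution of one state, conditional on surviving the cycle.
# Returns a named numeric vector: label -> probability. Errors when the
# composed branch masses leave [0, 1] (inconsistent parameter overrides).
survivor_successors <- function(state, strategy, plist) {
  acc <- new.env(parent = emptyenv())
  add <- function(s, p) {
    if (p < -1e-12)
      stop("transition composition produced a negative probability; ",
           "check parameter overrides", call. = FALSE)
    if (p <= 0) return(invisible())
    lbl <- state_label(s)
    assign(lbl, p + (if (exists(lbl, acc)) get(lbl, acc) else 0), acc)
  }
  cl <- state$clinical
  if (cl == "DEAD") {
    add(st_dead(), 1)
  } else if (cl == "SVL") {
    add(st_svl(next_tenure(state$svl_tenure), state$ever_prp), 1)
  } else if (cl == "PDR") {
    therapy <- if (state$line == "first") strategy$first else strategy$second
    tp <- pdr_treatment_probs(therapy, plist)
    line2 <- if (strategy$two_line && state$line == "first") "second"
             else state$line
    everT <- state$ever_prp || therapy == "PRP"
    pL <- pv(plist, "p_loss_followup")
    pS <- pv(plist, "p_PDR_to_SVL")
    pD <- pv(plist, "p_PDR_to_DME")
    if (pS + pD > 1)
      stop("p_PDR_to_SVL + p_PDR_to_DME exceeds 1", call. = FALSE)
    # lost to follow-up this cycle: no therapy, no line switch
    add(st_svl("1", state$ever_prp), pL * pS)
    add(st_dme("PDR", state$line, NA_character_, state$ever_prp), pL * pD)
    add(st_pdr(state$line, state$ever_prp), pL * (1 - pS - pD))
    # treated this cycle
    treated <- 1 - pL
    e_inj <- if (therapy == "antiVEGF") endo_svl_prob(plist, 3) else 0
    add(st_svl("1", everT), treated * e_inj)
    rem <- treated * (1 - e_inj)
    add(st_npdr(state$line, therapy, everT), rem * tp[["success"]])
    fail <- rem * (1 - tp[["success"]])
    add(st_svl("1", everT), fail * pS)
    add(st_dme("PDR", line2, NA_character_, everT), fail * pD)
    add(st_pdr(line2, everT), fail * (1 - pS - pD))
  } else if (cl == "NPDR") {
    r <- pdr_treatment_probs(state$last, plist)[["recurrence"]]
    pD <- pv(plist, "p_NPDR_to_DME")
    if (r + pD > 1)
      stop("NPDR recurrence + p_NPDR_to_DME exceeds 1", call. = FALSE)
    add(st_pdr(state$line, state$ever_prp), r)
    add(st_dme("NPDR", state$line, state$last, state$ever_prp), pD)
    add(st_npdr(state$line, state$last, state$ever_prp), 1 - r - pD)
  } else if (cl == "DME") {
    e_inj <- endo_svl_prob(plist, 3)
    s <- pv(plist, "p_antiVEGF_DME_success")
    add(st_svl("1", state$ever_prp), e_inj)
    origin <- if (state$dme_origin == "PDR") st_pdr(state$line, state$ever_prp)
              else st_npdr(state$line, state$last, state$ever_prp)
    add(origin, (1 - e_inj) * s)
    add(st_dme(state$dme_origin, state$line, state$last, state$ever_prp),
        (1 - e_inj) * (1 - s))
  }
  out <- mget(ls(acc), acc)
  stats::setNames(as.numeric(out), names(out))
}

# cache: state space depends only on the strategy
state_space_cache <- new.env(parent = emptyenv())

#' Enumerate the reachable state space of a strategy
#'
#' Starts from the initial state — PDR, first-line therapy pending, never
#' treated with PRP — and closes over the successor structure (using
#' base-case parameters, under which every branch has positive mass), then
#' orders the states deterministically by clinical state and attributes.
#' Each strategy reaches only its legal subset: single-line strategies have
#' no second-line states, and the anti-VEGF-only strategy has no post-PRP
#' states.
#'
#' @param strategy A strategy name or [strategy_spec()].
#' @return A tibble of class `pdr_state_space` with one row per reachable
#'   state: `label`, `clinical`, `line`, `last`, `ever_prp`, `dme_origin`,
#'   `svl_tenure`; the initial state is recorded in the `start_label`
#'   attribute.
#' @export
build_state_space <- function(strategy) {
  strategy <- strategy_spec(strategy)
  key <- strategy$name
  if (!is.null(state_space_cache[[key]])) return(state_space_cache[[key]])
  plist <- param_values(default_parameters())
  start <- st_pdr("first", FALSE)
  seen <- new.env(parent = emptyenv())
  assign(state_label(start), start, seen)
  queue <- list(start)
  while (length(queue) > 0) {
    s <- queue[[1]]
    queue <- queue[-1]
    succ_labels <- names(survivor_successors(s, strategy, plist))
    for (lbl in succ_labels) {
      if (!exists(lbl, seen)) {
        assign(lbl, parse_label(lbl), seen)
        queue <- c(queue, list(parse_label(lbl)))
      }
    }
  }
  # everyone can die
  assign("DEAD", st_dead(), seen)
  states <- mget(ls(seen), seen)
  tbl <- purrr::map_dfr(states, function(s) {
    tibble::tibble(label = state_label(s), clinical = s$clinical,
                   line = s$line, last = s$last, ever_prp = s$ever_prp,
                   dme_origin = s$dme_origin, svl_tenure = s$svl_tenure)
  })
  tbl <- dplyr::arrange(
    tbl,
    factor(.data$clinical, levels = c("NPDR", "PDR", "DME", "SVL", "DEAD")),
    factor(.data$dme_origin, levels = c("NPDR", "PDR")),
    factor(.data$line, levels = c("first", "second")),
    factor(.data$last, levels = c("PRP", "antiVEGF")),
    factor(.data$svl_tenure, levels = svl_tenures),
    .data$ever_prp)
  out <- structure(tbl,
                   class = c("pdr_state_space", "tbl_df", "tbl", "data.frame"),
                   start_label = state_label(start))
  state_space_cache[[key]] <- out
  out
}

# inverse of state_label
parse_label <- function(lbl) {
  if (lbl == "DEAD") return(st_dead())
  parts <- strsplit(lbl, "|", fixed = TRUE)[[1]]
  head <- parts[1]
  ever <- parts[length(parts)] == "pvfd"
  if (head == "PDR") return(st_pdr(parts[2], ever))
  if (head == "NPDR") return(st_npdr(parts[2], parts[3], ever))
  if (head == "SVL") return(st_svl(sub("^t", "", parts[2]), ever))
  if (startsWith(head, "DME:")) {
    last <- if (parts[3] == ".") NA_character_ else parts[3]
    return(st_dme(sub("^DME:", "", head), parts[2], last, ever))
  }
  stop("unparseable state label: ", lbl, call. = FALSE)
}

# row list for iteration
space_states <- function(space) {
  purrr::map(space$label, parse_label)
}
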