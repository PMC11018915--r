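#' @keywords internal
"_PACKAGE"

## Condition labels: two sessions, each a baseline trot followed by an
## induced lameness (iFL = forelimb, iHL = hindlimb).
CONDITIONS <- c("baseline1", "iFL", "baseline2", "iHL")

## Baseline paired with each induced condition (same session/day).
SESSION_PAIRING <- c(iFL = "baseline1", iHL = "baseline2")

## Superficial muscles recorded bilaterally.
MUSCLES <- c("triceps", "latissimus", "gluteal", "biceps",
             "semitendinosus", "longissimus_T14", "longissimus_L1")

SIDES <- c("left", "right")

## Vertical-displacement channels every trial must carry (mm, positive up).
REQUIRED_LANDMARKS <- c("poll", "withers", "pelvis",
                        "tuber_coxae_left", "tuber_coxae_right",
                        "hoof_hind_left", "hoof_hind_right")

## Upper-body landmarks that get MinDiff/MaxDiff.
ASYM_LANDMARKS <- c("poll", "withers", "pelvis")

## Stride-phase (fraction of stride after ipsilateral hind impact) at which
## each muscle's activation burst is centred in the simulator.
BURST_PHASE <- c(triceps = 0.65, latissimus = 0.55, gluteal = 0.10,
                 biceps = 0.15, semitendinosus = 0.90,
                 longissimus_T14 = 0.25, longissimus_L1 = 0.30)

emg_channel_name <- function(muscle, side) paste(muscle, side, sep = "_")

`%||%` <- function(a, b) if (is.null(a)) b else a
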