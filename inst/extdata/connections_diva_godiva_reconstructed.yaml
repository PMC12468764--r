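# Reconstructed default connection list: 58 ROI pairs spanning the
# feedback (auditory/somatosensory loop) and feedforward (SMA/preSMA,
# basal ganglia, thalamus, cerebellum) speech motor control networks of
# the DIVA/GODIVA model family, left-lateralized with select right
# hemisphere connections (right vPMC, right cerebellum).
# This is a plausibility RECONSTRUCTION from the model ROI vocabulary,
# not an authoritative enumeration; supply your own list for real data.
# L./R. = left/right; see package docs for ROI abbreviations.
- [L.vMC, L.vPMC]
- [L.vMC, R.vPMC]
- [L.vPMC, R.vPMC]
- [L.vMC, L.vSC]
- [L.vPMC, L.vSC]
- [L.vSC, L.VPM]
- [L.VPM, L.vMC]
- [L.vMC, L.pAC]
- [L.vPMC, L.pAC]
- [L.pAC, L.PT]
- [L.pAC, L.pSTG]
- [L.PT, L.pSTG]
- [L.H, L.pAC]
- [L.H, L.PT]
- [L.H, L.pSTG]
- [L.MG, L.H]
- [L.MG, L.pAC]
- [L.pSTG, L.vPMC]
- [L.PT, L.vPMC]
- [L.pSTG, L.vMC]
- [L.PT, L.vMC]
- [L.pSTG, R.vPMC]
- [L.PT, R.vPMC]
- [R.vPMC, L.vSC]
- [L.MG, L.PT]
- [L.MG, L.pSTG]
- [L.pAC, L.vSC]
- [L.pSTG, L.vSC]
- [L.preSMA, L.SMA]
- [L.preSMA, L.pIFS]
- [L.SMA, L.vMC]
- [L.SMA, L.vPMC]
- [L.pIFS, L.vPMC]
- [L.pIFS, L.vMC]
- [L.GP, L.VA]
- [L.GP, L.VL]
- [L.VA, L.SMA]
- [L.VA, L.preSMA]
- [L.VL, L.vMC]
- [L.VL, L.vPMC]
- [L.GP, L.preSMA]
- [L.GP, L.SMA]
- [L.VA, L.pIFS]
- [L.aCb, L.vMC]
- [L.aCb, L.vPMC]
- [L.aCb, L.VL]
- [R.aCb, L.VL]
- [R.aCb, L.vMC]
- [R.aCb, L.vPMC]
- [R.aCb, L.SMA]
- [L.aCb, L.SMA]
- [L.aCb, L.VPM]
- [L.pCb, L.pIFS]
- [L.pCb, L.preSMA]
- [R.pCb, L.preSMA]
- [R.pCb, L.pIFS]
- [R.pCb, L.pSTG]
- [L.pCb, L.pSTG]
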