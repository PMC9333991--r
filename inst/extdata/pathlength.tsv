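# Differential pathlength factors for diffuse reflectance from the intact
# mouse skull, cm, by illumination wavelength.  Derived from published Monte
# Carlo estimates of visible-light penetration in rodent cortex: pathlength
# grows with wavelength as hemoglobin absorption falls across the 450-660 nm
# window.  Intermediate wavelengths are obtained by linear interpolation.
# These factors scale the recovered concentration changes; analyses in this
# package use only relative/differential quantities.  Version 1.
wavelength_nm	pathlength_cm
450	0.05
470	0.06
490	0.08
510	0.10
530	0.10
550	0.11
570	0.12
590	0.15
610	0.35
630	0.55
650	0.70
660	0.75
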