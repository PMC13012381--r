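# Red-bone-marrow dosimetry factors for the three-parameter MEAC method:
# ratio of mass energy-absorption coefficients (mu_en/rho)_RBM /
# (mu_en/rho)_spongiosa and dose enhancement factor (DEF) for active
# marrow, per skeletal site, versus photon energy.
# SYNTHETIC stand-in table: published skeletal-dosimetry factors of this
# kind are not redistributable here, so these values are reconstructed
# from the package's embedded marrow/spongiosa energy-absorption data
# with site-dependent marrow-fraction offsets and a smooth DEF peaking
# near 50 keV where photoelectrons from trabecular bone enhance the
# marrow dose. Interpolate log-linearly in energy.
site,energy_keV,meac_ratio,def
femora,10,0.383,1.03
femora,20,0.338,1.09
femora,30,0.326,1.17
femora,40,0.341,1.25
femora,50,0.383,1.29
femora,60,0.450,1.27
femora,80,0.617,1.19
femora,100,0.758,1.12
femora,150,0.919,1.05
pelvis,10,0.395,1.03
pelvis,20,0.348,1.08
pelvis,30,0.336,1.16
pelvis,40,0.352,1.23
pelvis,50,0.395,1.27
pelvis,60,0.464,1.25
pelvis,80,0.636,1.18
pelvis,100,0.781,1.11
pelvis,150,0.947,1.05
sacrum,10,0.407,1.02
sacrum,20,0.358,1.07
sacrum,30,0.346,1.15
sacrum,40,0.363,1.22
sacrum,50,0.407,1.25
sacrum,60,0.478,1.24
sacrum,80,0.655,1.17
sacrum,100,0.804,1.10
sacrum,150,0.975,1.05
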