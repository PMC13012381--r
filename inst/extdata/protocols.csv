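hospital,site,vendor_model,kvp,mas,ctdiw_mGy,n_projections,start_angle,stop_angle,scan_length_cm,fov_cm,fan_mode,bowtie,notes
C,pelvis,Elekta Agility,120,1056,22.0,660,-180,180,41,27,half,elekta_half,Vendor provided
G1,pelvis,Elekta Agility,120,528,11.0,330,90,-89,28,42,half,elekta_half,Vendor provided
A3,pelvis,Varian ClinaciX,125,659,17.8,650,182,-178,11,30,half,varian_half,Vendor provided
D1,pelvis,Varian TrueBeam,125,1080,16.0,900,90,270,15,45,half,varian_half,Vendor provided
F1,pelvis,Varian Trilogy,125,697,17.8,670,180,-180,16,45,half,varian_half,Vendor provided
F6,pelvis,Varian Halcyon,125,592,11.8,529,-180,180,22,21,half,varian_half,Vendor provided
H1 60mA,pelvis,Varian TrueBeam,125,900,13.3,900,180,-180,21,45,full,varian_full,Full fan filter. Optimized on site
H1 80mA,pelvis,Varian Halcyon,125,1074,21.5,895,181,-181,25,45,half,varian_half,Vendor provided
O2,pelvis,Varian TrueBeam,125,684,11.5,900,-180,180,16,45,half,varian_half,Start-stop angles assumed
G1,prostate,Elekta Agility,120,528,11.0,330,90,-89,28,42,half,elekta_half,
M1,prostate,Elekta VersaHD,120,845,12.2,660,-180,180,21,28,half,elekta_half,
M4 narrow,prostate,Elekta Synergy,120,422,5.7,330,-180,180,14,28,half,elekta_half,
M4 wide,prostate,Elekta Synergy,120,422,7.8,330,-180,180,28,28,half,elekta_half,
F2,prostate,Varian TrueBeam,125,1080,16.0,900,180,-179,18,49,half,varian_half,
J,prostate,Varian TrueBeam,125,252,3.70,900,-179,181,16,45,half,varian_half,
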