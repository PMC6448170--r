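# Default piecewise-linear HU -> mass density (g/cm^3) calibration.
# Nodes anchor HU -1000 to standard air density and HU 0 to water; segments
# follow the four-group (air-fat / fat-water / soft / skeletal) scheme.
# Density is clamped to the end values outside [-1500, 2000].
hu,density_g_cm3
-1500,0.001205
-1000,0.001205
-104,0.930
0,1.000
160,1.100
2000,2.120
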