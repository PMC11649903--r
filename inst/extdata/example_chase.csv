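"time_min","signal","nu_mM","observable","label","replicate"
0,1.00568777487944,0,"mono_band","sim k1=0.015 k2=0.00038 k3=0.002 E2L0=1 nu=0 sigma=0.02 seed=20",1
10,0.836344479839675,0,"mono_band","sim k1=0.015 k2=0.00038 k3=0.002 E2L0=1 nu=0 sigma=0.02 seed=20",1
20,0.726684014132373,0,"mono_band","sim k1=0.015 k2=0.00038 k3=0.002 E2L0=1 nu=0 sigma=0.02 seed=20",1
30,0.656593241521056,0,"mono_band","sim k1=0.015 k2=0.00038 k3=0.002 E2L0=1 nu=0 sigma=0.02 seed=20",1
40,0.517110424948368,0,"mono_band","sim k1=0.015 k2=0.00038 k3=0.002 E2L0=1 nu=0 sigma=0.02 seed=20",1
50,0.482762736509324,0,"mono_band","sim k1=0.015 k2=0.00038 k3=0.002 E2L0=1 nu=0 sigma=0.02 seed=20",1
60,0.444818057681256,0,"mono_band","sim k1=0.015 k2=0.00038 k3=0.002 E2L0=1 nu=0 sigma=0.02 seed=20",1
70,0.374705711884023,0,"mono_band","sim k1=0.015 k2=0.00038 k3=0.002 E2L0=1 nu=0 sigma=0.02 seed=20",1
80,0.334871725679443,0,"mono_band","sim k1=0.015 k2=0.00038 k3=0.002 E2L0=1 nu=0 sigma=0.02 seed=20",1
90,0.320919170353556,0,"mono_band","sim k1=0.015 k2=0.00038 k3=0.002 E2L0=1 nu=0 sigma=0.02 seed=20",1
100,0.257135787046347,0,"mono_band","sim k1=0.015 k2=0.00038 k3=0.002 E2L0=1 nu=0 sigma=0.02 seed=20",1
110,0.242262159462338,0,"mono_band","sim k1=0.015 k2=0.00038 k3=0.002 E2L0=1 nu=0 sigma=0.02 seed=20",1
120,0.197428892124909,0,"mono_band","sim k1=0.015 k2=0.00038 k3=0.002 E2L0=1 nu=0 sigma=0.02 seed=20",1
0,0.992632272052441,250,"mono_band","sim k1=0.015 k2=0.00038 k3=0.002 E2L0=1 nu=250 sigma=0.02 seed=20",1
10,0.35054585527587,250,"mono_band","sim k1=0.015 k2=0.00038 k3=0.002 E2L0=1 nu=250 sigma=0.02 seed=20",1
20,0.125046493925561,250,"mono_band","sim k1=0.015 k2=0.00038 k3=0.002 E2L0=1 nu=250 sigma=0.02 seed=20",1
30,0.0468999744667316,250,"mono_band","sim k1=0.015 k2=0.00038 k3=0.002 E2L0=1 nu=250 sigma=0.02 seed=20",1
40,0.0362732371820228,250,"mono_band","sim k1=0.015 k2=0.00038 k3=0.002 E2L0=1 nu=250 sigma=0.02 seed=20",1
50,0.0252235817743062,250,"mono_band","sim k1=0.015 k2=0.00038 k3=0.002 E2L0=1 nu=250 sigma=0.02 seed=20",1
60,0.008994045718476,250,"mono_band","sim k1=0.015 k2=0.00038 k3=0.002 E2L0=1 nu=250 sigma=0.02 seed=20",1
70,-0.00769280300816159,250,"mono_band","sim k1=0.015 k2=0.00038 k3=0.002 E2L0=1 nu=250 sigma=0.02 seed=20",1
80,0.0291343549477396,250,"mono_band","sim k1=0.015 k2=0.00038 k3=0.002 E2L0=1 nu=250 sigma=0.02 seed=20",1
90,0.042935411337217,250,"mono_band","sim k1=0.015 k2=0.00038 k3=0.002 E2L0=1 nu=250 sigma=0.02 seed=20",1
100,-0.00130293915454283,250,"mono_band","sim k1=0.015 k2=0.00038 k3=0.002 E2L0=1 nu=250 sigma=0.02 seed=20",1
110,0.0276851894736404,250,"mono_band","sim k1=0.015 k2=0.00038 k3=0.002 E2L0=1 nu=250 sigma=0.02 seed=20",1
120,0.00952394480371147,250,"mono_band","sim k1=0.015 k2=0.00038 k3=0.002 E2L0=1 nu=250 sigma=0.02 seed=20",1
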