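site,P1g,P0g,varP,Q1g,Q0g,varQ,Pmax1g,Pmax0g,varPmax,PP1g,PP0g,varPP,nsdP,nsdQ
ascending_aorta,92.61,83.19,-10.17,87.85,80.01,-8.92,121.03,104.82,-13.39,51.04,39.66,-22.30,0.19,0.28
thoracic_aorta,92.38,82.99,-10.16,67.07,62.20,-7.26,129.83,114.49,-11.82,61.77,51.04,-17.37,0.24,0.37
abdominal_aorta_A,90.29,81.12,-10.16,46.95,44.04,-6.20,123.92,109.98,-11.25,58.75,48.83,-16.89,0.31,0.37
abdominal_aorta_E,90.76,81.45,-10.26,17.01,16.02,-5.82,135.38,119.27,-11.90,72.78,60.26,-17.20,0.33,0.47
external_iliac,90.48,80.93,-10.55,6.31,5.86,-7.13,135.07,119.46,-11.56,74.55,62.15,-16.63,0.34,0.49
femoral,89.47,80.20,-10.36,3.24,2.94,-9.26,135.63,119.75,-11.71,76.97,63.71,-17.23,0.37,0.56
ha_veins,6.94,6.54,-5.76,20.82,17.86,-14.22,7.33,6.84,-6.68,0.72,0.64,-11.11,0.56,0.56
l_vertebral,92.47,83.13,-10.10,1.60,1.33,-16.88,133.17,117.39,-11.85,65.80,54.55,-17.10,0.25,0.32
l_vertebral_arterioles,70.60,64.86,-8.13,1.61,1.34,-16.77,82.67,74.08,-10.39,25.66,19.77,-22.95,0.25,0.23
l_internal_carotid,92.27,83.03,-10.01,2.16,1.76,-18.52,140.36,124.19,-11.52,74.99,62.99,-16.00,0.30,0.43
l_internal_carotid_arterioles,80.40,73.32,-8.81,2.18,1.78,-18.35,101.30,90.77,-10.40,39.52,32.47,-17.84,0.26,0.27
l_external_carotid,92.28,83.05,-10.00,2.34,1.90,-18.80,141.51,125.13,-11.58,76.19,63.99,-16.01,0.30,0.41
l_external_carotid_arterioles,80.37,73.32,-8.77,2.35,1.93,-17.87,100.25,89.30,-10.92,38.03,30.53,-19.72,0.23,0.25
LA,7.51,7.39,-1.60,87.91,80.11,-8.87,8.67,8.54,-1.50,2.49,2.27,-8.84,0.26,0.34
LV,43.20,39.59,-8.36,87.85,80.01,-8.92,121.27,105.10,-13.33,118.26,101.38,-14.27,0.13,0.28
RA,6.47,6.14,-5.10,87.90,80.15,-8.82,7.93,7.42,-6.43,3.12,3.12,0.00,0.41,0.44
RV,11.64,10.95,-5.93,87.84,80.04,-8.88,23.56,21.08,-10.53,20.40,17.73,-13.09,0.15,0.23
pulmonary_arteries,15.42,14.59,-5.38,87.83,80.02,-8.89,23.35,20.92,-10.41,13.49,10.93,-18.98,0.16,0.17
pulmonary_veins,8.39,8.19,-2.38,87.86,80.05,-8.89,9.10,8.68,-4.62,1.21,0.83,-31.40,0.31,0.23
svc,6.48,6.15,-5.09,20.80,17.85,-14.18,9.09,8.59,-5.50,4.77,5.00,4.82,0.51,0.49
ivc,6.50,6.17,-5.08,67.16,62.35,-7.16,7.91,7.14,-9.73,2.73,1.83,-32.97,0.46,0.44
intercostals,92.64,83.22,-10.17,9.93,8.85,-10.88,141.78,124.59,-12.12,74.57,61.88,-17.02,0.29,0.49
intercostals_arterioles,85.39,76.74,-10.13,9.89,8.85,-10.52,115.90,103.48,-10.72,51.63,43.67,-15.42,0.26,0.28
l_brachial,92.33,82.97,-10.14,4.29,3.85,-10.27,130.85,115.57,-11.68,63.59,52.85,-16.89,0.25,0.42
gastric,89.36,80.44,-9.98,4.92,4.41,-10.37,130.97,116.02,-11.41,67.09,56.02,-16.50,0.31,0.32
gastric_arterioles,48.88,44.05,-9.88,4.92,4.42,-10.16,56.93,50.23,-11.77,16.94,13.02,-23.14,0.28,0.31
celiac_A,91.57,82.26,-10.17,10.17,9.19,-9.63,135.66,119.61,-11.83,70.55,58.49,-17.09,0.30,0.39
l_renal,90.43,81.23,-10.17,8.50,7.81,-8.12,127.89,113.58,-11.19,64.44,53.80,-16.51,0.27,0.32
l_renal_arterioles,66.18,58.90,-11.00,4.19,3.68,-12.17,78.37,68.11,-13.09,24.92,18.91,-24.12,0.30,0.33
u_abd_venules,12.94,11.90,-8.04,26.35,23.44,-11.04,13.64,12.39,-9.16,1.60,1.15,-28.12,0.30,0.30
l_abd_venules,12.98,12.38,-4.62,23.64,22.68,-4.06,13.81,13.03,-5.65,1.74,1.38,-20.69,0.33,0.33
inner_iliac,90.47,81.17,-10.28,2.20,2.15,-2.27,137.60,121.48,-11.72,76.79,63.97,-16.69,0.34,0.48
inner_iliac_arterioles,78.65,69.59,-11.52,2.20,2.15,-2.27,105.54,90.17,-14.56,46.21,35.46,-23.26,0.34,0.35
deep_femoral,89.44,80.17,-10.36,3.08,2.93,-4.87,136.30,120.03,-11.94,77.21,63.70,-17.50,0.37,0.48
deep_femoral_arterioles,68.12,59.74,-12.30,3.07,2.93,-4.56,86.66,73.92,-14.70,33.69,25.66,-23.83,0.38,0.37
anterior_tibial,84.44,75.61,-10.46,2.01,1.77,-11.94,144.32,124.92,-13.44,91.07,73.91,-18.84,0.48,0.54
anterior_tibial_arterioles,38.20,34.16,-10.58,2.01,1.78,-11.44,45.93,40.33,-12.19,14.13,10.91,-22.79,0.45,0.60
posterior_tibial,84.90,76.00,-10.48,1.22,1.15,-5.74,144.91,125.36,-13.49,91.46,74.11,-18.97,0.48,0.63
posterior_tibial_arterioles,64.36,56.33,-12.48,1.23,1.16,-5.69,85.48,72.87,-14.75,35.96,27.65,-23.11,0.48,0.52
legs_capillaries,27.13,25.63,-5.53,17.02,16.04,-5.76,31.59,29.23,-7.47,8.30,6.71,-19.16,0.40,0.40
legs_veins,7.68,7.28,-5.21,17.03,16.04,-5.81,7.78,7.32,-5.91,0.25,0.11,-56.00,0.50,0.50
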