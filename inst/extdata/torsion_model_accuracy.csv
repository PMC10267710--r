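preset_deg,goniometer,software
0,189.5,189.6
+10,199.5,199.7
+20,209.5,209.7
+30,219.5,219.4
+40,229.5,229.6
+50,239.5,239.6
+90,279.5,276.7
-10,179.5,179.6
-20,169.5,169.7
-30,159.5,159.5
-40,149.5,149.0
-50,139.5,139.5
-90,99.5,99.8
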