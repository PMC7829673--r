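wavelength_nm	eps_HbO	eps_HbR
650	0.03680	0.37501
660	0.03196	0.32266
670	0.02940	0.27951
680	0.02776	0.24079
690	0.02760	0.20520
700	0.02900	0.17943
710	0.03140	0.15405
720	0.03480	0.13259
730	0.03900	0.11022
740	0.04460	0.11159
750	0.05180	0.14052
760	0.05860	0.15485
770	0.06500	0.13119
780	0.07100	0.10754
790	0.07740	0.08908
800	0.08160	0.07617
810	0.08640	0.07235
820	0.09160	0.06938
830	0.09740	0.06930
840	0.10220	0.06924
850	0.10580	0.06913
860	0.10920	0.06917
870	0.11240	0.06981
880	0.11540	0.07062
890	0.11780	0.07211
900	0.11980	0.07318
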