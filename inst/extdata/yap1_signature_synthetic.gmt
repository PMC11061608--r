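YAP1_SCLC_synthetic	synthetic 49-gene stand-in for a YAP1-program signature	YSG001	YSG002	YSG003	YSG004	YSG005	YSG006	YSG007	YSG008	YSG009	YSG010	YSG011	YSG012	YSG013	YSG014	YSG015	YSG016	YSG017	YSG018	YSG019	YSG020	YSG021	YSG022	YSG023	YSG024	YSG025	YSG026	YSG027	YSG028	YSG029	YSG030	YSG031	YSG032	YSG033	YSG034	YSG035	YSG036	YSG037	YSG038	YSG039	YSG040	YSG041	YSG042	YSG043	YSG044	YSG045	YSG046	YSG047	YSG048	YSG049
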