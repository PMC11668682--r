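>SYNTRAJ01
ASDYKLNGFGQGTRTLVP
>SYNTRAJ02
ASDYKLTGFGQGTRILVK
>SYNTRAJ03
ATDYKLSAFGQGTRSLVE
>SYNTRAJ04
STDYKLGSFGQGTRALVD
>SYNTRAJ05
SADYKLASFGQGTRNLVG
>SYNTRAJ06
SADYKLNNFGKGTRTLVP
>SYNTRAJ07
TNDYKLTNFGKGTKILVK
>SYNTRAJ08
TNDYKLSTFGKGTKSLVE
>SYNTRAJ09
TGDYKLGTFGKGTKALVD
>SYNTRAJ10
NGDYKLAAFGRGTKNLVG
>SYNTRAJ11
NSDYKLNGFGRGTKTLVP
>SYNTRAJ12
NSDYKLTSFGRGTSILVK
>SYNTRAJ13
GTDYKLSAFGSGTSSLVE
>SYNTRAJ14
GADYKLGTFGSGTSALVD
>SYNTRAJ15
ANDYKLANLGSGSSNLIG
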