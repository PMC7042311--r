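channel	TS1	TS2	TS3	TS4	TS5	TS6
A[C>A]A	0.055907	0.001431	0.001031	0.001359	0.001389	0.000691
A[C>A]C	0.08711	0.001196	0.001773	0.000802	0.000545	0.001672
A[C>A]G	0.08711	0.000676	0.000682	0.001035	0.001103	0.001156
A[C>A]T	0.044855	0.001249	0.001	0.001644	0.000818	0.001433
C[C>A]A	0.061757	0.000793	0.001622	0.001631	0.001467	0.000691
C[C>A]C	0.038355	0.00104	0.001925	0.000608	0.001285	0.000742
C[C>A]G	0.039655	0.001144	0.001819	0.001424	0.001584	0.001156
C[C>A]T	0.054606	0.001483	0.000758	0.000751	0.00109	0.001458
G[C>A]A	0.037704	0.001808	0.001485	0.000595	0.00148	0.001006
G[C>A]C	0.069558	0.001327	0.001076	0.000725	0.000779	0.001345
G[C>A]G	0.030554	0.001183	0.001576	0.001488	0.001337	0.000666
G[C>A]T	0.08841	0.000949	0.001364	0.000557	0.001519	0.001408
T[C>A]A	0.08516	0.001131	0.000743	0.001437	0.001688	0.00054
T[C>A]C	0.057857	0.001561	0.001197	0.001113	0.000675	0.000754
T[C>A]G	0.033804	0.001392	0.001864	0.000738	0.000896	0.001295
T[C>A]T	0.036404	0.001665	0.001152	0.001023	0.001337	0.001596
A[C>G]A	0.001469	0.083885	0.002061	0.001048	0.000701	0.000528
A[C>G]C	0.001508	0.081934	0.001925	0.000906	0.001168	0.001596
A[C>G]G	0.000624	0.068929	0.001212	0.000531	0.001298	0.001709
A[C>G]T	0.000728	0.039016	0.001258	0.0011	0.001233	0.000591
C[C>G]A	0.001248	0.068929	0.00144	0.00167	0.001571	0.001672
C[C>G]C	0.000585	0.07283	0.000834	0.000569	0.00174	0.001722
C[C>G]G	0.001404	0.080634	0.00191	0.000828	0.001714	0.000679
C[C>G]T	0.001105	0.026011	0.00097	0.001372	0.001688	0.000716
G[C>G]A	0.00117	0.031213	0.000834	0.001385	0.00148	0.00093
G[C>G]C	0.000936	0.031213	0.001834	0.001644	0.00161	0.001068
G[C>G]G	0.000572	0.07218	0.001879	0.001424	0.001389	0.001609
G[C>G]T	0.001677	0.066328	0.000864	0.001799	0.00087	0.00132
T[C>G]A	0.001391	0.079333	0.001334	0.001411	0.000753	0.00132
T[C>G]C	0.001248	0.033164	0.001212	0.001437	0.000766	0.000754
T[C>G]G	0.001521	0.026011	0.001697	0.000777	0.00148	0.000591
T[C>G]T	0.001313	0.040967	0.001303	0.000828	0.000558	0.001257
A[C>T]A	0.000572	0.000871	0.090937	0.000518	0.000805	0.000691
A[C>T]C	0.001469	0.00121	0.071234	0.000867	0.001259	0.000691
A[C>T]G	0.001261	0.001379	0.036375	0.000557	0.000766	0.001357
A[C>T]T	0.001326	0.001457	0.038648	0.000802	0.000675	0.001181
C[C>T]A	0.00182	0.001288	0.059867	0.000608	0.001259	0.000641
C[C>T]C	0.001014	0.000975	0.050773	0.001437	0.001597	0.001559
C[C>T]G	0.001508	0.001183	0.085632	0.001488	0.001064	0.001244
C[C>T]T	0.000884	0.001587	0.042437	0.000919	0.001467	0.001094
G[C>T]A	0.001794	0.001275	0.035617	0.000764	0.001636	0.001043
G[C>T]C	0.00182	0.001418	0.039406	0.000932	0.000805	0.000515
G[C>T]G	0.001053	0.001756	0.080327	0.001566	0.001	0.001357
G[C>T]T	0.001066	0.001131	0.053804	0.000777	0.000519	0.000804
T[C>T]A	0.000728	0.001183	0.052289	0.001696	0.001623	0.001533
T[C>T]C	0.000975	0.001053	0.0485	0.00066	0.000597	0.001383
T[C>T]G	0.001768	0.000845	0.043195	0.000777	0.001337	0.000578
T[C>T]T	0.001508	0.000598	0.065171	0.001411	0.001	0.00083
A[T>A]A	0.000936	0.001053	0.000985	0.041418	0.001207	0.001571
A[T>A]C	0.000559	0.001613	0.001228	0.038829	0.001649	0.001056
A[T>A]G	0.001495	0.000845	0.001122	0.077012	0.000662	0.001144
A[T>A]T	0.001495	0.000585	0.000758	0.04789	0.000792	0.001068
C[T>A]A	0.001209	0.001053	0.000894	0.028475	0.000948	0.000993
C[T>A]C	0.000559	0.001118	0.001804	0.06148	0.000779	0.001458
C[T>A]G	0.001742	0.000689	0.000788	0.085425	0.001558	0.001068
C[T>A]T	0.001443	0.001118	0.001637	0.026533	0.001675	0.000855
G[T>A]A	0.000975	0.001574	0.00097	0.058891	0.000662	0.001722
G[T>A]C	0.001443	0.000663	0.001319	0.078306	0.000636	0.001094
G[T>A]G	0.001508	0.0016	0.001955	0.027181	0.000714	0.000918
G[T>A]T	0.001443	0.001548	0.000637	0.033652	0.001337	0.00083
T[T>A]A	0.001001	0.001288	0.000925	0.088661	0.001791	0.001496
T[T>A]C	0.001404	0.001626	0.001758	0.087366	0.001623	0.000691
T[T>A]G	0.000663	0.00173	0.001046	0.080247	0.001181	0.00176
T[T>A]T	0.001482	0.001053	0.000758	0.053714	0.001545	0.001672
A[T>C]A	0.001235	0.001249	0.00141	0.001035	0.056469	0.001546
A[T>C]C	0.001586	0.001457	0.000682	0.001204	0.04933	0.00132
A[T>C]G	0.000559	0.001053	0.002122	0.000815	0.034401	0.001131
A[T>C]T	0.00104	0.001561	0.000955	0.000699	0.052575	0.001609
C[T>C]A	0.000533	0.001327	0.000909	0.000958	0.071398	0.001357
C[T>C]C	0.000936	0.001574	0.001955	0.001631	0.073345	0.001307
C[T>C]G	0.001443	0.001444	0.001819	0.001255	0.083081	0.000641
C[T>C]T	0.001014	0.001118	0.000818	0.000582	0.046733	0.000679
G[T>C]A	0.000546	0.001795	0.001122	0.001747	0.090221	0.000855
G[T>C]C	0.001651	0.000572	0.001425	0.001048	0.075941	0.001458
G[T>C]G	0.000611	0.001405	0.000621	0.001268	0.067504	0.000842
G[T>C]T	0.000845	0.001587	0.001379	0.001721	0.071398	0.000603
T[T>C]A	0.000663	0.000572	0.001455	0.001385	0.038944	0.001546
T[T>C]C	0.000936	0.00065	0.001167	0.000725	0.027261	0.000993
T[T>C]G	0.00065	0.000585	0.002046	0.00145	0.036348	0.001144
T[T>C]T	0.000702	0.001483	0.002076	0.000647	0.030506	0.001395
A[T>G]A	0.000975	0.001678	0.002076	0.000893	0.001597	0.071644
A[T>G]C	0.000676	0.000806	0.00141	0.000621	0.001194	0.050277
A[T>G]G	0.000897	0.001418	0.00141	0.001191	0.00148	0.047763
A[T>G]T	0.000975	0.001379	0.001273	0.000673	0.000571	0.060332
C[T>G]A	0.001612	0.000767	0.001485	0.000802	0.001298	0.066616
C[T>G]C	0.001001	0.000676	0.000621	0.00066	0.001155	0.061589
C[T>G]G	0.001014	0.001483	0.000758	0.000595	0.001077	0.061589
C[T>G]T	0.001079	0.000754	0.001137	0.000971	0.001129	0.049648
G[T>G]A	0.001209	0.001314	0.00197	0.000686	0.001778	0.040221
G[T>G]C	0.0013	0.00121	0.001713	0.00101	0.001714	0.06913
G[T>G]G	0.001118	0.001379	0.000773	0.001204	0.00074	0.072272
G[T>G]T	0.001157	0.001183	0.002107	0.000802	0.00135	0.025767
T[T>G]A	0.001261	0.001587	0.001076	0.001411	0.001285	0.084213
T[T>G]C	0.001235	0.000741	0.001258	0.001178	0.000974	0.04085
T[T>G]G	0.001534	0.001808	0.001061	0.001204	0.001311	0.076672
T[T>G]T	0.000767	0.001418	0.001485	0.001411	0.000714	0.031423
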